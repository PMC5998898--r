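#' Readers and writers
#'
#' All per-residue data travels as plain TSV (diffable, desk-scale); models
#' are single JSON documents. A protein bundle is a directory with a
#' `manifest.tsv` naming each protein's feature and angle files.
#'
#' @name io
NULL

#' Read a 66-column feature TSV
#'
#' Expects a header row with the canonical [feature_columns()] names
#' (extra leading annotation columns `pos` and `aa` are accepted and kept).
#' Comment lines starting with `#` are ignored. CRLF and LF files parse
#' identically.
#'
#' @param path file path.
#' @return a tibble with the 66 feature columns (plus any annotation
#'   columns present).
#' @export
read_feature_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  fc <- feature_columns()
  if (!all(fc %in% header)) {
    stop("feature TSV header is missing ", sum(!fc %in% header),
         " of the 66 canonical columns (line ", lineno[1L], ")",
         call. = FALSE)
  }
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nc <- lengths(cells)
  if (any(nc != length(header))) {
    bad <- which(nc != length(header))[1L]
    stop("line ", lineno[-1L][bad], ": expected ", length(header),
         " columns, found ", nc[bad], call. = FALSE)
  }
  m <- do.call(rbind, cells)
  colnames(m) <- header
  out <- tibble::as_tibble(m)
  num_cols <- setdiff(header, c("pos", "aa", "protein", "ss"))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(out[[cn]]))
    if (anyNA(v) & !all(out[[cn]] %in% c("NA", "nan"))) {
      bad <- which(is.na(v) & out[[cn]] != "NA")[1L]
      if (!is.na(bad)) {
        stop("line ", lineno[-1L][bad], ": non-numeric value '",
             out[[cn]][bad], "' in column ", cn, call. = FALSE)
      }
    }
    out[[cn]] <- v
  }
  if ("pos" %in% header) out$pos <- as.integer(out$pos)
  out
}

#' Write a feature TSV
#'
#' @param data tibble with the 66 [feature_columns()] (annotation columns
#'   `pos`, `aa` are written first if present).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(data, path) {
  fc <- feature_columns()
  lead <- intersect(c("pos", "aa"), names(data))
  out <- as.data.frame(data[, c(lead, fc)])
  for (cn in fc) out[[cn]] <- sprintf("%.6g", out[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-Q` output dialect: two header lines, then one row per
#' residue with position, residue letter, 20 log-odds integers, 20
#' percentages and two trailing statistics. Only the 20 log-odds columns
#' are used. The file's residue-column order (A R N D C Q E G H I L K M F
#' P S T V W Y) is remapped to this package's alphabetical order.
#'
#' @param path file path.
#' @return a list with `sequence` (letter vector) and `pssm` (L x 20
#'   matrix, alphabetical column order).
#' @export
read_pssm_ascii <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  # locate the column-header line: 40 amino-acid letters
  hdr <- which(vapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    length(f) >= 20L && all(f[1:20] %in% AA_ALPHABET)
  }, logical(1)))[1L]
  if (is.na(hdr)) stop("malformed PSSM: no column header found", call. = FALSE)
  file_order <- strsplit(trimws(lines[hdr]), "\\s+")[[1]][1:20]
  rows <- list(); seqs <- character()
  for (i in seq.int(hdr + 1L, length(lines))) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L || is.na(suppressWarnings(as.integer(f[1L])))) break
    v <- suppressWarnings(as.numeric(f[3:22]))
    if (anyNA(v)) {
      stop("malformed PSSM row at line ", i, call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- v
    seqs[length(seqs) + 1L] <- f[2L]
  }
  if (!length(rows)) stop("malformed PSSM: no residue rows", call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- file_order
  m <- m[, AA_ALPHABET, drop = FALSE]
  list(sequence = seqs, pssm = unname(m))
}

#' Serialize a cluster model to JSON
#'
#' The written document round-trips bit-exactly through
#' [read_cluster_model()]: numeric values are stored as full-precision
#' (`%.17g`) strings.
#'
#' @param model an `angle_clusters` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "angle_clusters"))
  num <- function(x) sprintf("%.17g", x)
  doc <- list(
    type = "angle_clusters",
    k = model$k,
    seed = model$seed,
    sizes = model$sizes,
    raw_centers = apply(model$raw_centers, 1L, num, simplify = FALSE),
    centers = apply(model$centers, 1L, num, simplify = FALSE),
    background = num(model$background),
    circ_mean_phi = num(model$circ_mean_phi),
    circ_mean_psi = num(model$circ_mean_psi),
    var_phi = num(model$var_phi),
    var_psi = num(model$var_psi),
    bvm = lapply(model$bvm, function(b) {
      if (is.null(b)) NULL else lapply(unclass(b), num)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a cluster model from JSON
#'
#' @param path path written by [write_cluster_model()].
#' @return an `angle_clusters` object.
#' @export
read_cluster_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "angle_clusters")) {
    stop("not an angle_clusters JSON document: ", path, call. = FALSE)
  }
  num <- function(x) as.numeric(unlist(x))
  mat <- function(x) do.call(rbind, lapply(x, num))
  centers <- mat(doc$centers)
  colnames(centers) <- c("v0", "v1", "v2", "v3")
  raw <- mat(doc$raw_centers)
  model <- structure(
    list(
      k = as.integer(doc$k),
      raw_centers = raw,
      centers = centers,
      center_angles = to_angles(centers),
      background = num(doc$background),
      circ_mean_phi = num(doc$circ_mean_phi),
      circ_mean_psi = num(doc$circ_mean_psi),
      var_phi = num(doc$var_phi),
      var_psi = num(doc$var_psi),
      bvm = lapply(doc$bvm, function(b) {
        if (is.null(b)) NULL else
          bvm_params(as.numeric(b$mu), as.numeric(b$nu),
                     as.numeric(b$kappa1), as.numeric(b$kappa2),
                     as.numeric(b$kappa3))
      }),
      sizes = as.integer(unlist(doc$sizes)),
      seed = as.integer(doc$seed)
    ),
    class = "angle_clusters"
  )
  model
}

#' Serialize a classifier checkpoint to JSON
#'
#' @param model an `angle_classifier`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "angle_classifier"))
  num <- function(x) sprintf("%.17g", x)
  matj <- function(m) list(dim = dim(m), data = num(as.numeric(m)))
  doc <- list(
    type = "angle_classifier",
    k = model$k, hidden = model$hidden, n_blocks = model$n_blocks,
    half_window = model$half_window, lambda = model$lambda,
    seed = model$seed,
    center = num(model$center), scale = num(model$scale),
    W0 = matj(model$par$W0), b0 = num(model$par$b0),
    Wb = lapply(model$par$Wb, matj),
    bb = lapply(model$par$bb, num),
    Wo = matj(model$par$Wo), bo = num(model$par$bo),
    log = as.list(model$log)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a classifier checkpoint
#'
#' @param path path written by [write_classifier()].
#' @return an `angle_classifier`.
#' @export
read_classifier <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "angle_classifier")) {
    stop("not an angle_classifier JSON document: ", path, call. = FALSE)
  }
  num <- function(x) as.numeric(unlist(x))
  matr <- function(m) matrix(num(m$data), unlist(m$dim)[1L], unlist(m$dim)[2L])
  structure(
    list(
      par = list(
        W0 = matr(doc$W0), b0 = num(doc$b0),
        Wb = lapply(doc$Wb, matr), bb = lapply(doc$bb, num),
        Wo = matr(doc$Wo), bo = num(doc$bo)),
      k = as.integer(doc$k), hidden = as.integer(doc$hidden),
      n_blocks = as.integer(doc$n_blocks),
      half_window = as.integer(doc$half_window),
      lambda = as.numeric(doc$lambda), seed = as.integer(doc$seed),
      center = num(doc$center), scale = num(doc$scale),
      log = tibble::as_tibble(lapply(doc$log, unlist))
    ),
    class = "angle_classifier"
  )
}

#' Write per-residue predictions as TSV
#'
#' Header `# pos aa phi psi std_phi std_psi top_label top_prob`; angles to
#' two decimals; masked values as `NA`.
#'
#' @param pred an `angle_prediction` tibble.
#' @param path output path.
#' @param aa optional amino-acid letters (defaults to `X`).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path, aa = NULL) {
  if (is.null(aa)) aa <- rep("X", nrow(pred))
  f2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  lines <- c(
    "# pos aa phi psi std_phi std_psi top_label top_prob",
    sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%d\t%s",
            pred$pos, aa, f2(pred$phi_pred), f2(pred$psi_pred),
            f2(pred$std_phi), f2(pred$std_psi), pred$top_label,
            f2(pred$top_prob)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a residue tibble as a protein bundle directory
#'
#' Creates `manifest.tsv` plus, per protein, `<id>.features.tsv` (66
#' feature columns) and `<id>.angles.tsv` (`pos`, `aa`, `ss`, `phi`,
#' `psi`, `basin` when present; masked angles as `NA`).
#'
#' @param data residue tibble from [generate_protein_set()] (or the same
#'   schema).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_protein_bundle <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- unique(data$protein)
  rows <- purrr::map(ids, function(id) {
    d <- data[data$protein == id, ]
    ff <- paste0(id, ".features.tsv")
    af <- paste0(id, ".angles.tsv")
    write_feature_tsv(d, file.path(dir, ff))
    acols <- intersect(c("pos", "aa", "ss", "phi", "psi", "basin"), names(d))
    ad <- as.data.frame(d[, acols])
    for (cn in intersect(c("phi", "psi"), acols)) {
      ad[[cn]] <- ifelse(is.na(ad[[cn]]), "NA", sprintf("%.6f", ad[[cn]]))
    }
    utils::write.table(ad, file.path(dir, af), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tibble::tibble(protein = id, length = nrow(d), features = ff, angles = af)
  })
  utils::write.table(dplyr::bind_rows(rows), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a protein bundle directory
#'
#' @param dir directory written by [write_protein_bundle()].
#' @return a residue tibble with the same schema as
#'   [generate_protein_set()].
#' @export
read_protein_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv in ", dir, call. = FALSE)
  man <- utils::read.delim(mf, stringsAsFactors = FALSE)
  out <- purrr::map(seq_len(nrow(man)), function(i) {
    feats <- read_feature_tsv(file.path(dir, man$features[i]))
    ang <- utils::read.delim(file.path(dir, man$angles[i]),
                             stringsAsFactors = FALSE, na.strings = "NA")
    if (nrow(feats) != nrow(ang)) {
      stop("length mismatch between feature and angle files for ",
           man$protein[i], call. = FALSE)
    }
    dplyr::bind_cols(
      tibble::tibble(protein = man$protein[i]),
      tibble::as_tibble(ang),
      feats[, feature_columns()])
  })
  dplyr::bind_rows(out)
}
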