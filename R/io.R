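#' Read a regional time-series matrix from TSV/CSV
#'
#' The file must be a rectangular numeric table, one row per region, one
#' column per time point. The delimiter (tab or comma) is sniffed from the
#' first line. Non-numeric or non-finite cells and ragged rows are rejected
#' with the offending row and column named.
#'
#' @param path file path.
#' @param region_labels optional character vector of region names; length
#'   must match the number of rows.
#' @param transpose set to `TRUE` if the file stores time points as rows.
#' @return numeric matrix (regions x time points) with region labels as row
#'   names.
#' @export
read_timeseries <- function(path, region_labels = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty file: ", path)
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  m <- length(parts[[1]])
  X <- matrix(NA_real_, length(parts), m)
  for (r in seq_along(parts)) {
    if (length(parts[[r]]) != m)
      stop(sprintf("ragged table in %s: row %d has %d fields, expected %d",
                   path, r, length(parts[[r]]), m))
    v <- suppressWarnings(as.numeric(parts[[r]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite value in %s at row %d, column %d",
                   path, r, bad[[1]]))
    X[r, ] <- v
  }
  if (transpose) X <- t(X)
  validate_timeseries(X)
  if (!is.null(region_labels)) {
    if (length(region_labels) != nrow(X))
      stop(sprintf("region table has %d names but matrix has %d rows",
                   length(region_labels), nrow(X)))
    rownames(X) <- region_labels
  } else {
    rownames(X) <- default_region_labels(nrow(X))
  }
  X
}

format_row <- function(v) paste(sprintf("%.17g", v), collapse = "\t")

#' Write a regional time-series matrix as TSV
#'
#' Values are written at full double precision so that a write/read
#' round-trip is exact to better than 1e-12.
#'
#' @param X numeric matrix (regions x time points).
#' @param path output file path.
#' @export
write_timeseries <- function(X, path) {
  validate_timeseries(X)
  writeLines(vapply(seq_len(nrow(X)), function(r) format_row(X[r, ]), ""),
             path)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' A manifest is a TSV with header `subject_id`, `label`, `path`; labels must
#' come from `{patient, control}` and subject ids must be unique.
#'
#' @param path manifest file path.
#' @return data.frame with the three columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  bad <- setdiff(unique(df$label), c("patient", "control"))
  if (length(bad))
    stop("unknown label(s) in manifest: ", paste(bad, collapse = ", "))
  df[need]
}

#' Write a cohort manifest
#' @param manifest data.frame with columns `subject_id`, `label`, `path`.
#' @param path output file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a connectivity network with its construction parameters
#'
#' The file begins with a `# key=value` comment header recording the network
#' kind and its parameters, followed by the tab-separated matrix at full
#' double precision.
#'
#' @param C an `fbn_network`.
#' @param path output file path.
#' @export
write_network <- function(C, path) {
  stopifnot(inherits(C, "fbn_network"))
  p <- network_params(C)
  hdr <- c(sprintf("# kind=%s", network_kind(C)),
           sprintf("# n=%d", nrow(C)),
           sprintf("# regions=%s", paste(attr(C, "region_labels"),
                                         collapse = ",")))
  for (nm in names(p)) hdr <- c(hdr, sprintf("# %s=%.17g", nm, p[[nm]]))
  v <- unclass(C)
  writeLines(c(hdr, vapply(seq_len(nrow(v)), function(r) format_row(v[r, ]), "")),
             path)
  invisible(path)
}

#' Read a connectivity network written by [write_network()]
#'
#' @param path file path.
#' @return an `fbn_network` with kind and parameters restored.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)=(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[[2]]]] <- m[[3]]
  }
  vals <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
  if (any(!is.finite(vals))) stop("non-finite value in network file: ", path)
  if (nrow(vals) != ncol(vals)) stop("network matrix is not square: ", path)
  if (max(abs(vals - t(vals))) > 1e-8)
    stop("network matrix is not symmetric: ", path)
  kind <- kv$kind %||% "first_order"
  labels <- if (!is.null(kv$regions)) strsplit(kv$regions, ",", fixed = TRUE)[[1]]
            else NULL
  params <- list()
  for (nm in c("k", "mu", "threshold")) {
    if (!is.null(kv[[nm]])) {
      x <- as.numeric(kv[[nm]])
      params[[nm]] <- if (nm == "k") as.integer(round(x)) else x
    }
  }
  fbn_network(vals, kind, params = params, region_labels = labels)
}

#' Write a cohort to disk as per-subject TSVs plus a manifest
#'
#' @param cohort an `fbn_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly; the manifest file is
#'   `manifest.tsv` in `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$subject_ids, ".tsv"))
  for (s in seq_along(cohort$subjects)) {
    X <- cohort$subjects[[s]]
    rownames(X) <- cohort$region_labels
    write_timeseries(X, paths[[s]])
  }
  manifest <- data.frame(subject_id = cohort$subject_ids,
                         label = as.character(cohort$labels),
                         path = basename(paths),   # manifest-relative
                         stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Load a cohort from a manifest
#'
#' @param manifest_path path to a manifest TSV (see [read_manifest()]);
#'   relative subject paths are resolved against the manifest's directory.
#' @param region_labels optional region names applied to every subject.
#' @return an `fbn_cohort`.
#' @export
read_cohort <- function(manifest_path, region_labels = NULL) {
  manifest <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  subjects <- lapply(manifest$path, function(p) {
    if (!file.exists(p) && file.exists(file.path(base, p)))
      p <- file.path(base, p)
    read_timeseries(p, region_labels)
  })
  dims <- vapply(subjects, function(x) paste(dim(x), collapse = "x"), "")
  if (length(unique(dims)) != 1)
    stop("subjects have inconsistent dimensions: ", paste(unique(dims), collapse = ", "))
  structure(list(subjects = subjects,
                 labels = factor(manifest$label, levels = c("control", "patient")),
                 subject_ids = manifest$subject_id,
                 region_labels = rownames(subjects[[1]]), spec = NULL),
            class = "fbn_cohort")
}
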