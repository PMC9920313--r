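#' Frequency table of voxel spacings across a dataset
#'
#' @param spacings a list of numeric length-3 spacings, or a 3-column matrix
#'   (one row per scan, `(x, y, z)` mm).
#' @return An object of class `spacing_table`: a data frame with columns
#'   `sx`, `sy`, `sz`, `count`.
#' @export
spacing_table <- function(spacings) {
  if (is.matrix(spacings)) spacings <- asplit(spacings, 1)
  if (!length(spacings))
    stop("spacing_table: no spacings given", call. = FALSE)
  m <- do.call(rbind, lapply(spacings, function(s) {
    s <- as.numeric(s)
    if (length(s) != 3L || any(!is.finite(s)) || any(s <= 0))
      stop("spacing_table: each spacing must be 3 positive numbers",
           call. = FALSE)
    s
  }))
  key <- apply(m, 1, paste, collapse = "|")
  tab <- table(key)
  parts <- do.call(rbind, lapply(strsplit(names(tab), "|", fixed = TRUE),
                                 as.numeric))
  out <- data.frame(sx = parts[, 1], sy = parts[, 2], sz = parts[, 3],
                    count = as.integer(tab))
  class(out) <- c("spacing_table", "data.frame")
  out
}

#' Select the dataset-wide common spacing
#'
#' Picks the most frequent spacing in the table; ties are broken toward the
#' smaller spacing (ascending lexicographic order on `(x, y, z)`), which
#' minimizes interpolation when the rest of the dataset is resampled to it.
#'
#' @param table a [spacing_table()] (or a data frame with columns
#'   `sx`, `sy`, `sz`, `count`).
#' @return Numeric length-3 spacing `(x, y, z)` in mm.
#' @export
select_common_spacing <- function(table) {
  if (is.null(table) || nrow(table) == 0L)
    stop("select_common_spacing: empty spacing table", call. = FALSE)
  ord <- order(-table$count, table$sx, table$sy, table$sz)
  as.numeric(unlist(table[ord[1], c("sx", "sy", "sz")]))
}

#' Form weak CT–CBCT pairs for evaluation
#'
#' For each patient, selects the (CT, CBCT) pair with the smallest absolute
#' acquisition-date difference, keeping it only when that difference is at
#' most one day (larger gaps risk real anatomical change). Ties are broken
#' deterministically toward the earlier CT date, then the earlier CBCT date.
#' Patients without a qualifying pair are omitted. Deformable registration
#' of the chosen CT to its CBCT is left to external tooling; this function
#' emits the pair manifest.
#'
#' @param records data frame of scan records with columns `patient_id`,
#'   `modality`, `date`, `path` (see [read_scan_metadata()]).
#' @param max_delta_days maximum allowed date difference (default 1).
#' @return A data frame with columns `patient_id`, `ct_path`, `cbct_path`,
#'   `delta_days`; zero rows if no patient qualifies.
#' @export
select_weak_pairs <- function(records, max_delta_days = 1L) {
  if (!all(c("patient_id", "modality", "date", "path") %in% names(records)))
    stop("select_weak_pairs: records need patient_id, modality, date, path",
         call. = FALSE)
  dates <- suppressWarnings(tryCatch(as.Date(records$date),
                                     error = function(e) NA))
  if (length(dates) != nrow(records) || any(is.na(dates))) {
    probe <- suppressWarnings(lapply(records$date, function(d)
      tryCatch(as.Date(d), error = function(e) as.Date(NA))))
    bad <- which(is.na(unlist(probe)) | vapply(probe, is.na, logical(1)))
    stop("select_weak_pairs: unparseable date in record(s) ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  records$date <- dates
  out <- list()
  for (pid in unique(records$patient_id)) {
    sub <- records[records$patient_id == pid, , drop = FALSE]
    cts <- sub[sub$modality == "CT", , drop = FALSE]
    cbs <- sub[sub$modality == "CBCT", , drop = FALSE]
    if (nrow(cts) == 0L || nrow(cbs) == 0L) next
    grid <- expand.grid(i = seq_len(nrow(cts)), j = seq_len(nrow(cbs)))
    grid$delta <- abs(as.integer(cts$date[grid$i] - cbs$date[grid$j]))
    grid <- grid[grid$delta <= max_delta_days, , drop = FALSE]
    if (nrow(grid) == 0L) next
    grid <- grid[order(grid$delta, cts$date[grid$i], cbs$date[grid$j]), ,
                 drop = FALSE]
    best <- grid[1, ]
    out[[length(out) + 1L]] <- data.frame(
      patient_id = pid, ct_path = cts$path[best$i],
      cbct_path = cbs$path[best$j], delta_days = best$delta,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(patient_id = character(), ct_path = character(),
                      cbct_path = character(), delta_days = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
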