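# Study data model: counts + biomass + perturbation schedules per subject.

#' Construct a microbiome time-series dataset
#'
#' Bundles per-subject observation times, taxon count matrices, total-biomass
#' measurements and perturbation schedules into a validated `mb_dataset`.
#' Counts are sequencing reads (compositional); biomass restores the absolute
#' concentration scale.
#'
#' @param counts named list, one integer matrix (taxa x time points, rownames =
#'   taxon labels) per subject.
#' @param biomass named list, one numeric vector per subject; `NA` marks a
#'   missing biomass measurement. Present values must be positive.
#' @param times named list, one strictly increasing numeric vector of days per
#'   subject.
#' @param perturbations named list of perturbation schedules as returned by
#'   [perturbation_schedule()].
#' @param taxa character vector of taxon labels (defaults to the rownames of
#'   the first count matrix).
#' @param events optional named list (per subject) of known dosing events,
#'   each a data.frame with columns `time`, `taxon`, `add` (concentration
#'   added at that time, e.g. an experimental infection challenge); used by
#'   forecasting so that known introductions are part of the forecast.
#' @param biomass_uninformative logical flag set by [strip_biomass()].
#' @return An object of class `mb_dataset` with elements `taxa`, `subjects`,
#'   `times`, `counts`, `readdepth`, `biomass`, `perturbations`.
#' @seealso [read_dataset()], [strip_biomass()], [hide_biomass()]
#' @export
mb_dataset <- function(counts, biomass, times, perturbations = list(),
                       taxa = rownames(counts[[1]]), events = list(),
                       biomass_uninformative = FALSE) {
  subjects <- names(counts)
  if (is.null(subjects)) stop("counts must be a named list (one entry per subject)")
  counts <- lapply(counts, function(m) {
    storage.mode(m) <- "double"
    m
  })
  ds <- structure(list(
    taxa = taxa,
    subjects = subjects,
    times = times[subjects],
    counts = counts,
    readdepth = lapply(counts, colSums),
    biomass = biomass[subjects],
    perturbations = perturbations,
    events = events,
    biomass_uninformative = biomass_uninformative
  ), class = "mb_dataset")
  validate_dataset(ds)
  ds
}

#' Validate an `mb_dataset`
#'
#' Checks the structural invariants: integer counts >= 0, at least two time
#' points per subject, strictly increasing days, positive read depths,
#' positive present biomass, and non-overlapping perturbation intervals.
#'
#' @param ds an `mb_dataset`.
#' @return `ds`, invisibly; errors describe the first violated invariant.
#' @export
validate_dataset <- function(ds) {
  for (s in ds$subjects) {
    tt <- ds$times[[s]]
    if (length(tt) < 2)
      stop(sprintf("subject '%s' has fewer than 2 time points", s))
    if (any(diff(tt) <= 0))
      stop(sprintf("days for subject '%s' are not strictly increasing", s))
    m <- ds$counts[[s]]
    if (!is.matrix(m) || nrow(m) != length(ds$taxa) || ncol(m) != length(tt))
      stop(sprintf("count matrix for subject '%s' is mis-dimensioned", s))
    if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
      stop(sprintf("counts for subject '%s' must be non-negative integers", s))
    if (any(colSums(m) == 0))
      stop(sprintf("subject '%s' has a sample with zero read depth (day %s)",
                   s, tt[which(colSums(m) == 0)[1]]))
    w <- ds$biomass[[s]]
    if (length(w) != length(tt))
      stop(sprintf("biomass vector for subject '%s' is mis-dimensioned", s))
    if (any(!is.na(w) & w <= 0))
      stop(sprintf("biomass for subject '%s' contains non-positive values", s))
  }
  for (p in ds$perturbations) {
    for (iv in p$intervals) {
      if (is.null(iv) || nrow(iv) == 0) next
      if (any(iv[, 2] <= iv[, 1])) stop("perturbation interval with end <= start")
      o <- order(iv[, 1])
      if (nrow(iv) > 1 && any(iv[o[-nrow(iv)], 2] > iv[o[-1], 1]))
        stop(sprintf("overlapping intervals in perturbation '%s'", p$id))
    }
  }
  invisible(ds)
}

#' @export
print.mb_dataset <- function(x, ...) {
  cat(sprintf("mb_dataset: %d taxa, %d subjects, %s time points/subject, %d perturbation(s)\n",
              length(x$taxa), length(x$subjects),
              paste(range(vapply(x$times, length, 1L)), collapse = "-"),
              length(x$perturbations)))
  if (isTRUE(x$biomass_uninformative))
    cat("  biomass flagged uninformative (mean-filled)\n")
  invisible(x)
}

#' Define a perturbation schedule
#'
#' A perturbation (diet shift, antibiotic, infection, ...) is a binary step
#' function of time per subject, represented as half-open day intervals
#' `[start, end)`: the indicator evaluates to 1 at `start` and 0 at `end`.
#'
#' @param id schedule label.
#' @param intervals named list (per subject) of two-column matrices
#'   `cbind(start, end)`; `end = Inf` encodes an ongoing perturbation.
#' @return An object of class `perturbation_schedule`.
#' @export
perturbation_schedule <- function(id, intervals) {
  intervals <- lapply(intervals, function(iv) {
    iv <- matrix(as.numeric(iv), ncol = 2)
    colnames(iv) <- c("start", "end")
    iv
  })
  structure(list(id = id, intervals = intervals),
            class = "perturbation_schedule")
}

#' Evaluate a perturbation indicator
#'
#' @param sched a `perturbation_schedule`.
#' @param subject subject id.
#' @param t numeric vector of days.
#' @return 0/1 vector: 1 where `t` lies in some `[start, end)` interval.
#' @export
pert_indicator <- function(sched, subject, t) {
  iv <- sched$intervals[[subject]]
  if (is.null(iv) || nrow(iv) == 0) return(rep(0, length(t)))
  vapply(t, function(ti) as.numeric(any(ti >= iv[, 1] & ti < iv[, 2])), 1)
}

# 0/1 indicator matrix (P x length(t)) for all schedules of a dataset.
pert_matrix <- function(ds, subject, t) {
  P <- length(ds$perturbations)
  if (P == 0) return(matrix(0, 0, length(t)))
  m <- t(vapply(ds$perturbations, pert_indicator, numeric(length(t)),
                subject = subject, t = t))
  matrix(m, nrow = P, ncol = length(t))
}

#' Read a dataset from TSV files
#'
#' Reads the three on-disk tables: a counts table (taxa as rows, one column
#' per sample, first column = taxon label), a biomass table (`sample_id`,
#' `biomass`; empty or `NA` cells mark missing measurements), and a metadata
#' table (`sample_id`, `subject`, `day`, plus one 0/1 column per perturbation).
#' Samples are ordered by day within subject; perturbation intervals are
#' reconstructed from the per-sample flags (a run of flagged samples becomes
#' `[first flagged day, day of the next unflagged sample)`, or `[.., Inf)` if
#' the run reaches the subject's last sample).
#'
#' @param counts_path,biomass_path,metadata_path file paths.
#' @return A validated [mb_dataset()].
#' @export
read_dataset <- function(counts_path, biomass_path, metadata_path) {
  cts <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read.delim(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  bio <- read.delim(biomass_path, check.names = FALSE, stringsAsFactors = FALSE)

  taxa <- as.character(cts[[1]])
  cmat <- as.matrix(cts[, -1, drop = FALSE])
  for (j in seq_len(ncol(cmat))) {
    col <- suppressWarnings(as.numeric(cmat[, j]))
    bad <- which(is.na(col) | col < 0 | col != round(col))
    if (length(bad))
      stop(sprintf("counts: non-integer or negative value at row '%s', column '%s'",
                   taxa[bad[1]], colnames(cmat)[j]))
  }
  storage.mode(cmat) <- "double"
  rownames(cmat) <- taxa

  need <- c("sample_id", "subject", "day")
  if (!all(need %in% names(meta)))
    stop("metadata must contain columns sample_id, subject, day")
  missing_meta <- setdiff(colnames(cmat), meta$sample_id)
  if (length(missing_meta))
    stop(sprintf("sample '%s' present in counts but absent from metadata",
                 missing_meta[1]))
  meta <- meta[match(colnames(cmat), meta$sample_id), , drop = FALSE]
  if (anyDuplicated(meta[, c("subject", "day")]))
    stop("duplicate (subject, day) pairs in metadata")
  pert_cols <- setdiff(names(meta), need)

  if (!all(c("sample_id", "biomass") %in% names(bio)))
    stop("biomass table must contain columns sample_id, biomass")
  wvals <- suppressWarnings(as.numeric(bio$biomass))
  names(wvals) <- bio$sample_id

  subjects <- unique(meta$subject)
  counts <- biomass <- times <- list()
  for (s in subjects) {
    rows <- which(meta$subject == s)
    rows <- rows[order(meta$day[rows])]
    times[[s]] <- meta$day[rows]
    counts[[s]] <- cmat[, meta$sample_id[rows], drop = FALSE]
    biomass[[s]] <- unname(wvals[meta$sample_id[rows]])
  }

  perts <- list()
  for (p in pert_cols) {
    intervals <- list()
    for (s in subjects) {
      rows <- which(meta$subject == s)
      rows <- rows[order(meta$day[rows])]
      flag <- as.numeric(meta[[p]][rows]) > 0
      days <- meta$day[rows]
      iv <- NULL
      r <- rle(flag)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in seq_along(r$values)) {
        if (!r$values[k]) next
        a <- days[starts[k]]
        b <- if (ends[k] < length(days)) days[ends[k] + 1] else Inf
        iv <- rbind(iv, c(a, b))
      }
      intervals[[s]] <- if (is.null(iv)) matrix(numeric(0), 0, 2) else iv
    }
    perts[[p]] <- perturbation_schedule(p, intervals)
  }

  mb_dataset(counts = counts, biomass = biomass, times = times,
             perturbations = perts, taxa = taxa)
}

#' Write a dataset back to TSV files
#'
#' Inverse of [read_dataset()]: emits counts, biomass and metadata tables so
#' that reading them back reproduces counts bit-exactly and biomass to full
#' printed precision.
#'
#' @param ds an `mb_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sample_id <- subject <- day <- character(0)
  cmat <- NULL
  w <- numeric(0)
  for (s in ds$subjects) {
    ids <- sprintf("%s_d%g", s, ds$times[[s]])
    sample_id <- c(sample_id, ids)
    subject <- c(subject, rep(s, length(ids)))
    day <- c(day, ds$times[[s]])
    cmat <- cbind(cmat, ds$counts[[s]])
    w <- c(w, ds$biomass[[s]])
  }
  colnames(cmat) <- sample_id
  meta <- data.frame(sample_id = sample_id, subject = subject,
                     day = as.numeric(day), check.names = FALSE)
  for (p in names(ds$perturbations)) {
    sch <- ds$perturbations[[p]]
    meta[[p]] <- unlist(lapply(ds$subjects, function(s)
      pert_indicator(sch, s, ds$times[[s]])))
  }
  paths <- file.path(dir, c("counts.tsv", "biomass.tsv", "metadata.tsv"))
  write.table(data.frame(taxon = ds$taxa, cmat, check.names = FALSE),
              paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = sample_id,
                         biomass = format(w, digits = 17), check.names = FALSE),
              paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Replace biomass by its grand mean ("no biomass" mode)
#'
#' Replaces every biomass measurement by the mean over all present values in
#' all subjects, so the biomass channel carries no temporal information. Used
#' to probe how much network inference depends on absolute abundance data.
#'
#' @param ds an `mb_dataset` with at least one non-missing biomass value.
#' @return The dataset with constant biomass and `biomass_uninformative = TRUE`.
#' @export
strip_biomass <- function(ds) {
  all_w <- unlist(ds$biomass)
  if (all(is.na(all_w))) stop("all biomass values are missing")
  m <- mean(all_w, na.rm = TRUE)
  ds$biomass <- lapply(ds$biomass, function(w) rep(m, length(w)))
  ds$biomass_uninformative <- TRUE
  ds
}

#' Flag selected biomass measurements as missing
#'
#' Emulates sparser biomass sampling by hiding measurements at given
#' (subject, day) pairs; counts are untouched.
#'
#' @param ds an `mb_dataset`.
#' @param hidden data.frame with columns `subject` and `day`.
#' @return The dataset with those biomass entries set to `NA`.
#' @export
hide_biomass <- function(ds, hidden) {
  if (NROW(hidden) == 0) return(ds)
  for (i in seq_len(nrow(hidden))) {
    s <- as.character(hidden$subject[i])
    d <- hidden$day[i]
    if (!s %in% ds$subjects) stop(sprintf("unknown subject '%s'", s))
    j <- which(ds$times[[s]] == d)
    if (length(j) != 1)
      stop(sprintf("no sample at (subject %s, day %g)", s, d))
    ds$biomass[[s]][j] <- NA_real_
  }
  ds
}
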