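GROUP_LEVELS <- c("control", "lTLE", "rTLE")

#' Subject record
#'
#' Bundles one participant's metadata and connectomes. Controls carry missing
#' (`NA`) clinical fields; clinical covariates are always encoded as explicit
#' missing values, never as zero.
#'
#' @param subject_id unique identifier.
#' @param group `"control"`, `"lTLE"` or `"rTLE"`.
#' @param age years.
#' @param sex `"F"` or `"M"`.
#' @param site acquisition site label (e.g. `"site256"`, `"site64"`).
#' @param duration_years epilepsy duration (patients) or `NA`.
#' @param is_hs hippocampal sclerosis flag (patients) or `NA`.
#' @param ied_per_min interictal-discharge rate, `>= 0`, or `NA`.
#' @param connectomes named list of [connectome()]s keyed `"fmri"`,
#'   `"eeg.delta"`, ... (see [group_average()]).
#' @return an object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group, age, sex, site,
                           duration_years = NA_real_, is_hs = NA,
                           ied_per_min = NA_real_, connectomes = list()) {
  group <- match.arg(group, GROUP_LEVELS)
  sex <- match.arg(sex, c("F", "M"))
  if (!is.na(ied_per_min) && ied_per_min < 0) {
    stop("ied_per_min must be non-negative", call. = FALSE)
  }
  if (group == "control" && (!is.na(duration_years) || !is.na(is_hs) ||
                             !is.na(ied_per_min))) {
    stop("controls must have missing clinical fields", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), group = group,
                 age = as.numeric(age), sex = sex, site = as.character(site),
                 duration_years = as.numeric(duration_years),
                 is_hs = as.logical(is_hs),
                 ied_per_min = as.numeric(ied_per_min),
                 connectomes = connectomes),
            class = "subject_record")
}

#' Cohort stack
#'
#' An ordered collection of subject records sharing one atlas; the unit all
#' group-level statistics operate on. All connectomes must share the atlas's
#' region count and subject ids must be unique.
#'
#' @param subjects list of [subject_record()]s.
#' @param atlas an [atlas_model()].
#' @return an object of class `cohort_stack`.
#' @export
cohort_stack <- function(subjects, atlas) {
  stopifnot(inherits(atlas, "atlas_model"))
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique", call. = FALSE)
  R <- n_regions(atlas)
  for (s in subjects) {
    for (cm in s$connectomes) {
      if (nrow(cm$values) != R) {
        stop(sprintf("subject %s has a %d-region connectome under a %d-region atlas",
                     s$subject_id, nrow(cm$values), R), call. = FALSE)
      }
    }
  }
  structure(list(subjects = subjects, atlas = atlas), class = "cohort_stack")
}

#' @export
print.cohort_stack <- function(x, ...) {
  grp <- vapply(x$subjects, function(s) s$group, character(1))
  cat(sprintf("<cohort_stack> %d subjects over %d regions\n",
              length(x$subjects), n_regions(x$atlas)))
  print(table(group = grp))
  invisible(x)
}

#' @keywords internal
stack_subjects <- function(stack, groups = NULL) {
  stopifnot(inherits(stack, "cohort_stack"))
  if (is.null(groups)) return(stack$subjects)
  Filter(function(s) s$group %in% groups, stack$subjects)
}

#' Subject-by-edge matrix for one modality/band
#'
#' @param stack a [cohort_stack()].
#' @param modality,band connectome selector.
#' @param groups optional group filter.
#' @return numeric matrix, one row per subject (rownames = subject ids),
#'   columns in canonical edge order.
#' @export
stack_edges <- function(stack, modality = "fmri", band = "none", groups = NULL) {
  subs <- stack_subjects(stack, groups)
  if (!length(subs)) stop("no subjects match the group filter", call. = FALSE)
  key <- connectome_key(modality, band)
  out <- t(vapply(subs, function(s) {
    cm <- s$connectomes[[key]]
    if (is.null(cm)) stop(sprintf("subject %s lacks connectome %s", s$subject_id, key),
                          call. = FALSE)
    vectorize_upper(cm$values)
  }, numeric(n_edges(n_regions(stack$atlas)))))
  rownames(out) <- vapply(subs, function(s) s$subject_id, character(1))
  out
}

#' @keywords internal
stack_groups <- function(stack, groups = NULL) {
  vapply(stack_subjects(stack, groups), function(s) s$group, character(1))
}

#' Read and write subject metadata tables
#'
#' Metadata is a TSV with header columns `subject_id, group, age, sex, site,
#' duration_years, is_hs, ied_per_min`; missing clinical values are written
#' as `NA`.
#'
#' @param path file path.
#' @return `read_metadata()`: a data.frame with the columns above.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("subject_id", "group", "age", "sex", "site",
            "duration_years", "is_hs", "ied_per_min")
  if (!all(need %in% names(tab))) {
    stop(sprintf("metadata must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  tab$is_hs <- as.logical(tab$is_hs)
  tab
}

#' @rdname read_metadata
#' @param stack a [cohort_stack()].
#' @export
write_metadata <- function(stack, path) {
  rows <- lapply(stack$subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               sex = s$sex, site = s$site, duration_years = s$duration_years,
               is_hs = s$is_hs, ied_per_min = s$ied_per_min,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Cohort subsetting for sensitivity analyses
#'
#' Re-runs of the main analysis on restricted cohorts: `ied_le_1` drops
#' patients with more than 1 interictal discharge per minute; `hs_only` /
#' `non_hs_only` stratify patients by hippocampal sclerosis. Controls are
#' always retained. An empty patient group after filtering is an error.
#'
#' @param stack a [cohort_stack()].
#' @param rule one of `"ied_le_1"`, `"hs_only"`, `"non_hs_only"`.
#' @return a filtered [cohort_stack()].
#' @export
sensitivity_filters <- function(stack, rule = c("ied_le_1", "hs_only", "non_hs_only")) {
  rule <- match.arg(rule)
  keep <- vapply(stack$subjects, function(s) {
    if (s$group == "control") return(TRUE)
    switch(rule,
           ied_le_1 = is.na(s$ied_per_min) || s$ied_per_min <= 1,
           hs_only = isTRUE(s$is_hs),
           non_hs_only = isFALSE(s$is_hs))
  }, logical(1))
  out <- stack$subjects[keep]
  grp <- vapply(out, function(s) s$group, character(1))
  lost <- setdiff(unique(stack_groups(stack)), unique(grp))
  if (length(lost)) {
    stop(sprintf("filter '%s' empties group(s): %s", rule,
                 paste(lost, collapse = ", ")), call. = FALSE)
  }
  cohort_stack(out, stack$atlas)
}
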