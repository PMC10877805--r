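#' Log-transformed WMH burden
#'
#' White matter hyperintensity volume is heavily right-skewed; its base-10
#' logarithm (volume in ml) is used as the CSVD burden measure, which centers
#' a typical low-lesion reference group near 0 (1 ml -> 0).
#'
#' @param wmh_volume_ml lesion volume in ml (> 0).
#' @param floor optional positive floor (ml) applied to zero/negative
#'   volumes; when `NULL` (default) such volumes are an error.
#' @param base logarithm base, 10 by default (configurable to `exp(1)`).
#' @return log-burden values.
#' @export
log_wmh_burden <- function(wmh_volume_ml, floor = NULL, base = 10) {
  if (anyNA(wmh_volume_ml)) stop("wmh_volume_ml contains NA")
  if (any(wmh_volume_ml <= 0)) {
    if (is.null(floor))
      stop("WMH volume <= 0 ml; pass floor = 0.01 (or another positive ",
           "floor in ml) to clamp empty segmentations explicitly")
    if (floor <= 0) stop("floor must be > 0")
    wmh_volume_ml <- pmax(wmh_volume_ml, floor)
  }
  log(wmh_volume_ml, base = base)
}

#' Head-size-normalized choroid plexus volume
#'
#' Choroid plexus volume in mm^3 divided by total intracranial volume in ml,
#' i.e. the mm^3/(ml x 10^3) volume ratio rescaled by 10^3, yielding values
#' near 1 for typical adults. Invariant to consistent unit rescaling of both
#' volumes.
#'
#' @param choroid_mm3 choroid plexus volume, mm^3 (>= 0).
#' @param tiv_ml total intracranial volume, ml (> 0).
#' @return normalized choroid plexus volume.
#' @export
normalize_choroid <- function(choroid_mm3, tiv_ml) {
  if (anyNA(choroid_mm3) || anyNA(tiv_ml)) stop("inputs contain NA")
  if (any(tiv_ml <= 0)) stop("tiv_ml must be > 0")
  if (any(choroid_mm3 < 0)) stop("choroid_mm3 must be >= 0")
  choroid_mm3 / tiv_ml
}

#' Basal ganglia PVS visual grade
#'
#' Grade 1: fewer than 5 PVS; grade 2: 5 to 10 (both ends inclusive);
#' grade 3: more than 10 but still countable; grade 4: uncountable.
#'
#' @param count PVS count (ignored where `countable` is `FALSE`).
#' @param countable logical; `FALSE` marks uncountable cases (grade 4).
#' @return integer grades in 1..4.
#' @export
rate_pvs_bg <- function(count, countable = TRUE) {
  n <- max(length(count), length(countable))
  count <- rep_len(count, n); countable <- rep_len(countable, n)
  if (any(countable & (is.na(count) | count < 0)))
    stop("count must be a non-negative number for countable cases")
  grade <- integer(n)
  grade[!countable] <- 4L
  cc <- which(countable)
  grade[cc] <- ifelse(count[cc] < 5, 1L, ifelse(count[cc] <= 10, 2L, 3L))
  grade
}

#' White matter (centrum semiovale) PVS visual grade
#'
#' Grade 1: fewer than 10 PVS in total; grade 2: 10 or more in total but no
#' more than 10 in any single section; grade 3: more than 10 and up to 20 in
#' the most affected section; grade 4: more than 20 in any single section.
#'
#' @param total_count total PVS count over all sections.
#' @param max_per_section count in the most affected single section
#'   (cannot exceed `total_count`).
#' @return integer grades in 1..4.
#' @export
rate_pvs_wm <- function(total_count, max_per_section) {
  if (anyNA(total_count) || anyNA(max_per_section))
    stop("counts contain NA")
  if (any(total_count < 0) || any(max_per_section < 0))
    stop("counts must be non-negative")
  if (any(max_per_section > total_count))
    stop("max_per_section cannot exceed total_count")
  ifelse(total_count < 10, 1L,
         ifelse(max_per_section <= 10, 2L,
                ifelse(max_per_section <= 20, 3L, 4L)))
}

#' Amyloid positivity from global SUVR
#'
#' Global AV45 SUVR strictly greater than 1.11 is amyloid positive.
#'
#' @param suvr global SUVR (> 0).
#' @param cutoff positivity threshold (default 1.11).
#' @return logical flags.
#' @export
amyloid_positive <- function(suvr, cutoff = 1.11) {
  if (anyNA(suvr) || any(suvr <= 0)) stop("suvr must be positive")
  suvr > cutoff
}

#' AD-continuum group assignment
#'
#' CN-: cognitively normal, amyloid negative, without severe CSVD (Fazekas
#' score below 2). CN+/MCI+/AD+: amyloid positive with the matching clinical
#' diagnosis. Everything else is excluded with a reason.
#'
#' @param diagnosis character: `"CN"`, `"MCI"` or `"dementia"`.
#' @param amyloid logical amyloid-positivity flag (see [amyloid_positive()]).
#' @param fazekas Fazekas WMH grade, 0..3.
#' @return character vector with levels `"CN-"`, `"CN+"`, `"MCI+"`, `"AD+"`
#'   or `"excluded"`; attribute `"reason"` holds the exclusion reason
#'   (`NA` for assigned records).
#' @export
assign_group <- function(diagnosis, amyloid, fazekas) {
  ok <- c("CN", "MCI", "dementia")
  if (!all(diagnosis %in% ok))
    stop("unknown diagnosis label(s): ",
         paste(unique(setdiff(diagnosis, ok)), collapse = ", "))
  n <- max(length(diagnosis), length(amyloid), length(fazekas))
  diagnosis <- rep_len(diagnosis, n)
  amyloid <- rep_len(amyloid, n); fazekas <- rep_len(fazekas, n)
  group <- rep("excluded", n)
  reason <- rep(NA_character_, n)
  group[diagnosis == "CN" & amyloid] <- "CN+"
  group[diagnosis == "MCI" & amyloid] <- "MCI+"
  group[diagnosis == "dementia" & amyloid] <- "AD+"
  cn_neg <- diagnosis == "CN" & !amyloid
  group[cn_neg & fazekas < 2] <- "CN-"
  reason[cn_neg & fazekas >= 2] <- "amyloid-negative CN with Fazekas >= 2"
  reason[diagnosis != "CN" & !amyloid] <- "amyloid-negative non-CN"
  structure(group, reason = reason)
}

#' Quality-control exclusions
#'
#' Drops records with a Geriatric Depression Scale score of 5 or more, a
#' chin-up head position (AC-PC angle strictly greater than 20 degrees), or
#' an amyloid-PET-to-DTI interval of 12 months or more. Reasons accumulate.
#'
#' @param records data frame with columns `gds`, `acpc_angle_deg`,
#'   `pet_dti_interval_months` (and optionally `id`).
#' @param lenient when `TRUE`, missing QC fields are tolerated (a missing
#'   field simply cannot trigger its exclusion); otherwise they are an error.
#' @return A data frame with columns `id`, `keep` (logical) and `reasons`
#'   (`;`-separated, `""` when kept).
#' @export
apply_exclusions <- function(records, lenient = FALSE) {
  needed <- c("gds", "acpc_angle_deg", "pet_dti_interval_months")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) && !lenient)
    stop("missing QC field(s): ", paste(missing_cols, collapse = ", "),
         " (use lenient = TRUE to skip these checks)")
  n <- nrow(records)
  get_col <- function(nm) if (nm %in% names(records)) records[[nm]] else
    rep(NA_real_, n)
  reasons <- vector("list", n)
  add <- function(idx, msg) for (i in which(idx))
    reasons[[i]] <<- c(reasons[[i]], msg)
  gds <- get_col("gds")
  add(!is.na(gds) & gds >= 5, "GDS >= 5")
  ang <- get_col("acpc_angle_deg")
  add(!is.na(ang) & ang > 20, "chin-up (AC-PC angle > 20 deg)")
  itv <- get_col("pet_dti_interval_months")
  add(!is.na(itv) & itv >= 12, "PET-DTI interval >= 12 months")
  if (!lenient) {
    bad <- is.na(gds) | is.na(ang) | is.na(itv)
    if (any(bad)) stop("QC fields contain NA for ", sum(bad),
                       " record(s); use lenient = TRUE to tolerate")
  }
  reasons_chr <- vapply(reasons, function(r)
    paste(r, collapse = "; "), character(1))
  data.frame(
    id = if ("id" %in% names(records)) records$id else seq_len(n),
    keep = reasons_chr == "",
    reasons = reasons_chr,
    stringsAsFactors = FALSE
  )
}

#' Vascular risk factor score
#'
#' Count of recorded vascular risk factors (hypertension, diabetes,
#' hyperlipidemia, smoking, heart disease), 0..5.
#'
#' @param records data frame holding the five 0/1 flag columns.
#' @return integer scores.
#' @export
vascular_risk_score <- function(records) {
  flags <- c("hypertension", "diabetes", "hyperlipidemia", "smoking",
             "heart_disease")
  missing_cols <- setdiff(flags, names(records))
  if (length(missing_cols))
    stop("missing vascular risk flag(s): ",
         paste(missing_cols, collapse = ", "))
  as.integer(rowSums(as.matrix(records[flags])))
}
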