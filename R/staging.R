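#' Default centiloid positivity thresholds by tracer
#'
#' Amyloid PET burden on the centiloid scale is classified positive at
#' tracer-specific cut-offs: 16.4 centiloids for Pittsburgh compound B (PiB)
#' and 20.6 for florbetapir, both inclusive.
#'
#' @export
amyloid_thresholds <- c(PiB = 16.4, florbetapir = 20.6)

#' Classify amyloid PET positivity from centiloid burden
#'
#' @param tracer Character vector, `"PiB"` or `"florbetapir"`.
#' @param centiloid Numeric centiloid values (finite).
#' @param thresholds Named positivity cut-offs (inclusive); defaults to
#'   [amyloid_thresholds].
#' @return Character vector, `"positive"` / `"negative"`.
#' @export
classify_amyloid <- function(tracer, centiloid,
                             thresholds = amyloid_thresholds) {
  if (!all(tracer %in% names(thresholds)))
    stopf("unknown tracer(s): %s",
          paste(setdiff(unique(tracer), names(thresholds)), collapse = ", "))
  if (any(!is.finite(centiloid))) stopf("centiloid values must be finite")
  unname(ifelse(centiloid >= thresholds[tracer], "positive", "negative"))
}

STAGE_LEVELS <- c("CS-", "CS+", "IMP+", "excluded")
EXCLUSION_REASONS <- c("none", "uncertain cognition", "missing amyloid",
                       "impaired amyloid-negative")

#' Assign disease-stage labels from amyloid and clinical status
#'
#' Stages: `CS-` (cognitively stable, amyloid negative), `CS+` (stable,
#' positive; preclinical), `IMP+` (mild cognitive impairment or dementia with
#' amyloid positivity; the two impaired categories are pooled). Every other
#' combination is excluded with a reason: undetermined cognition, missing
#' amyloid PET, or impairment despite a negative amyloid scan.
#'
#' @param amyloid Character vector in `{"positive", "negative", "missing"}`.
#' @param clinical Character vector in `{"CS", "MCI-DS", "DEM",
#'   "undetermined"}`.
#' @return Data frame with columns `stage` and `exclusion_reason`
#'   (`"none"` unless excluded). Total and deterministic over its domain.
#' @export
assign_stage <- function(amyloid, clinical) {
  n <- max(length(amyloid), length(clinical))
  amyloid <- rep_len(as.character(amyloid), n)
  clinical <- rep_len(as.character(clinical), n)
  ok_a <- amyloid %in% c("positive", "negative", "missing")
  ok_c <- clinical %in% c("CS", "MCI-DS", "DEM", "undetermined")
  if (!all(ok_a)) stopf("invalid amyloid status: %s",
                        paste(unique(amyloid[!ok_a]), collapse = ", "))
  if (!all(ok_c)) stopf("invalid clinical status: %s",
                        paste(unique(clinical[!ok_c]), collapse = ", "))
  stage <- rep("excluded", n)
  reason <- rep("none", n)
  impaired <- clinical %in% c("MCI-DS", "DEM")
  stage[amyloid == "negative" & clinical == "CS"] <- "CS-"
  stage[amyloid == "positive" & clinical == "CS"] <- "CS+"
  stage[amyloid == "positive" & impaired] <- "IMP+"
  exc <- stage == "excluded"
  # precedence: unknown cognition first, then missing PET, then the
  # impaired-but-negative discordance
  reason[exc & clinical == "undetermined"] <- "uncertain cognition"
  reason[exc & clinical != "undetermined" & amyloid == "missing"] <-
    "missing amyloid"
  reason[exc & impaired & amyloid == "negative"] <- "impaired amyloid-negative"
  data.frame(stage = factor(stage, levels = STAGE_LEVELS),
             exclusion_reason = factor(reason, levels = EXCLUSION_REASONS))
}

#' Split a stage group into derivation and withheld subsets
#'
#' Randomly withholds part of one stage group (by default the amyloid-negative
#' reference group) so signature derivation and ROC evaluation do not reuse
#' the same subjects. The derivation side gets `ceiling(fraction * n)`
#' members. A balance report (Welch t for age and centiloid, two-proportion
#' z for sex and APOE e4 carriage) accompanies the split.
#'
#' @param cohort A [generate_cohort()] cohort (or any list with a `subjects`
#'   data frame carrying `stage`, `age`, `centiloid`, `sex`, `apoe_e4`).
#' @param group Stage label to split (default `"CS-"`).
#' @param fraction Derivation fraction, in (0, 1); default 0.8.
#' @param seed Integer seed controlling membership.
#' @return Object of class `reference_split`: list with `group`,
#'   `derivation_ids`, `withheld_ids`, and `balance` (one row per tested
#'   variable with statistic and p value).
#' @export
split_reference <- function(cohort, group = "CS-", fraction = 0.8,
                            seed = 1L) {
  subj <- cohort$subjects
  if (!group %in% subj$stage) stopf("group '%s' not present in cohort", group)
  if (fraction <= 0 || fraction >= 1) stopf("'fraction' must lie in (0, 1)")
  ids <- subj$id[subj$stage == group]
  n <- length(ids)
  n_der <- ceiling(fraction * n)
  if (min(n_der, n - n_der) < 1L || fraction * n < 2)
    stopf("split of %d subjects at fraction %.2f leaves too few members",
          n, fraction)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  der <- sort(sample(ids, n_der))
  wit <- sort(setdiff(ids, der))
  g <- subj[match(c(der, wit), subj$id), ]
  side <- rep(c("derivation", "withheld"), c(length(der), length(wit)))
  balance <- rbind(
    balance_welch("age", g$age, side),
    balance_welch("centiloid", g$centiloid, side),
    balance_prop("sex_male", g$sex == "male", side),
    balance_prop("apoe_e4", g$apoe_e4, side)
  )
  structure(list(group = group, derivation_ids = der, withheld_ids = wit,
                 balance = balance),
            class = "reference_split")
}

balance_welch <- function(name, x, side) {
  tt <- stats::t.test(x[side == "derivation"], x[side == "withheld"])
  data.frame(variable = name, test = "welch_t",
             statistic = unname(tt$statistic), p_value = tt$p.value)
}

balance_prop <- function(name, x, side) {
  x1 <- x[side == "derivation"]; x2 <- x[side == "withheld"]
  p1 <- mean(x1); p2 <- mean(x2)
  n1 <- length(x1); n2 <- length(x2)
  p <- mean(x)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  data.frame(variable = name, test = "two_proportion_z",
             statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.reference_split <- function(x, ...) {
  cat(sprintf("reference_split of %s: %d derivation / %d withheld\n",
              x$group, length(x$derivation_ids), length(x$withheld_ids)))
  print(x$balance, row.names = FALSE)
  invisible(x)
}
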