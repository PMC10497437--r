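#' Configuration for a synthetic cohort run
#'
#' Assembles and validates the parameters of a phantom-cohort study
#' replica: patient phantoms carry one focal lesion each, volunteer
#' phantoms none; every phantom gets its own noise realization and a
#' random per-subject global intensity scale (scanner arbitrariness).
#' Lesion level frequencies default to the empirical distribution over
#' C3/4-C6/7 (6 : 15 : 22 : 6, none at C2/3).
#'
#' @param nCases,nControls Cohort sizes (>= 1).
#' @param seed Integer seed; mandatory, drives every random choice.
#' @param ageRange Uniform age bounds (years) for both cohorts.
#' @param lesionAmplitude Lesion peak intensity as a fraction of baseline.
#' @param lesionSigma Lesion axial Gaussian sigma, in slices.
#' @param lesionSharpness In-plane demarcation in (0, 1]; 1 = sharp.
#' @param noiseSigma Rician noise scale in a.u. (default 12.5 = 5% of the
#'   250 a.u. baseline).
#' @param raterError Per-rater probability of flipping the truth label when
#'   simulating subjective ratings (default 0.05, giving 3-rater unanimity
#'   rates in the mid-90s percent regime).
#' @param nRaters Odd number of simulated raters (default 3).
#' @param scaleRange Uniform bounds of the per-subject global scale.
#' @param levelWeights Named sampling weights of the lesion level.
#' @param dim,spacing,cordRadius,baseline Phantom geometry, see
#'   [PhantomSpec()].
#' @param sdDenominator Passed to [quantifySubject()].
#' @return A validated list of class `cordCohortConfig`.
#' @export
cohortConfig <- function(nCases = 30L, nControls = 30L, seed,
                         ageRange = c(40, 80), lesionAmplitude = 0.5,
                         lesionSigma = 4, lesionSharpness = 1,
                         noiseSigma = 12.5, raterError = 0.05, nRaters = 3L,
                         scaleRange = c(0.7, 1.3),
                         levelWeights = c("C3/4" = 6, "C4/5" = 15,
                                          "C5/6" = 22, "C6/7" = 6),
                         dim = c(64L, 64L, 120L),
                         spacing = c(0.6, 0.6, 1.0), cordRadius = 4.0,
                         baseline = 250, sdDenominator = "n-1") {
  if (missing(seed) || is.null(seed) || is.na(seed))
    .cordError("configError", "seed is mandatory in phantom-cohort mode")
  if (nCases < 1L || nControls < 1L)
    .cordError("configError", "nCases and nControls must be >= 1")
  if (nRaters < 3L || nRaters %% 2L == 0L)
    .cordError("configError", "nRaters must be odd and >= 3")
  if (raterError < 0 || raterError >= 0.5)
    .cordError("configError", "raterError must lie in [0, 0.5)")
  if (!all(names(levelWeights) %in% .CERVICAL_LEVELS))
    .cordError("configError", "levelWeights names must be cervical levels")
  cfg <- list(nCases = as.integer(nCases), nControls = as.integer(nControls),
              seed = as.integer(seed), ageRange = ageRange,
              lesionAmplitude = lesionAmplitude, lesionSigma = lesionSigma,
              lesionSharpness = lesionSharpness, noiseSigma = noiseSigma,
              raterError = raterError, nRaters = as.integer(nRaters),
              scaleRange = scaleRange, levelWeights = levelWeights,
              dim = as.integer(dim), spacing = spacing,
              cordRadius = cordRadius, baseline = baseline,
              sdDenominator = sdDenominator)
  class(cfg) <- "cordCohortConfig"
  cfg
}

#' Draw the cohort design: subjects, ages, lesions, phantom specs
#'
#' Deterministically expands a [cohortConfig()] into per-subject phantom
#' specifications. Patients receive one lesion at a sampled cervical level,
#' centered within that level's slice interval; volunteers receive none.
#'
#' @param config A `cordCohortConfig`.
#' @return Data frame with one row per subject: `subject`, `cohort`
#'   (`"patient"`/`"volunteer"`), `age`, `sex`, `lesion_level` (NA for
#'   volunteers), plus a list-column `spec` of [PhantomSpec-class] objects.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "cordCohortConfig"))
  .withSeed(config$seed, {
    n <- config$nCases + config$nControls
    subj <- c(sprintf("case%03d", seq_len(config$nCases)),
              sprintf("vol%03d", seq_len(config$nControls)))
    cohort <- rep(c("patient", "volunteer"),
                  c(config$nCases, config$nControls))
    age <- round(stats::runif(n, config$ageRange[1L], config$ageRange[2L]))
    sex <- sample(c("f", "m"), n, replace = TRUE)
    gs <- stats::runif(n, config$scaleRange[1L], config$scaleRange[2L])
    seeds <- sample.int(2^31 - 2, n)
    lm <- c(C2 = 10L, C3 = 28L, C4 = 46L, C5 = 64L, C6 = 82L, C7 = 100L)
    # rescale default landmarks if a non-default slice count is requested
    if (config$dim[3L] != 120L)
      lm <- round(lm / 120 * config$dim[3L])
    lev <- sample(names(config$levelWeights), config$nCases, replace = TRUE,
                  prob = config$levelWeights / sum(config$levelWeights))
    lesionLevel <- c(lev, rep(NA_character_, config$nControls))
    # zero amplitude means no hyperintensity exists: no lesion, no positives
    if (config$lesionAmplitude == 0) lesionLevel[] <- NA_character_
    bodies <- .CERVICAL_BODIES
    specs <- lapply(seq_len(n), function(i) {
      lesions <- list()
      if (!is.na(lesionLevel[i])) {
        k <- match(lesionLevel[i], .CERVICAL_LEVELS)
        lo <- lm[k]; hi <- lm[k + 1L]
        center <- round(stats::runif(1, lo + 0.3 * (hi - lo),
                                     hi - 0.3 * (hi - lo)))
        lesions <- list(LesionSpec(center, axialSigma = config$lesionSigma,
                                   amplitude = config$lesionAmplitude,
                                   sharpness = config$lesionSharpness,
                                   radius = config$cordRadius / 2))
      }
      PhantomSpec(dim = config$dim, spacing = config$spacing,
                  cordRadius = config$cordRadius, baseline = config$baseline,
                  landmarks = stats::setNames(lm, bodies), lesions = lesions,
                  noiseSigma = config$noiseSigma, globalScale = gs[i],
                  seed = seeds[i])
    })
    out <- data.frame(subject = subj, cohort = cohort, age = age, sex = sex,
                      lesion_level = lesionLevel, stringsAsFactors = FALSE)
    out$spec <- specs
    out
  })
}

#' Simulate multi-rater binary ratings from truth labels
#'
#' Plumbing for phantom mode (no human raters exist for synthetic data):
#' each simulated rater independently flips the truth label with
#' probability `errorRate`.
#'
#' @param truth Integer 0/1 vector of true segment labels.
#' @param nRaters Odd rater count.
#' @param errorRate Flip probability per rater and segment.
#' @return A [RatingTable-class].
#' @export
simulateRatings <- function(truth, nRaters = 3L, errorRate = 0.05) {
  flips <- matrix(stats::rbinom(length(truth) * nRaters, 1L, errorRate),
                  ncol = nRaters)
  RatingTable((matrix(truth, length(truth), nRaters) + flips) %% 2L)
}

#' Group comparison table in the style of a matched-pair results table
#'
#' For each quantification parameter and each cervical level with at least
#' one positive segment (plus the pooled "All" stratum), reports the
#' median (IQR) of the matched T2-negative and T2-positive groups and the
#' two-sided Mann-Whitney p-value.
#'
#' @param segStats Data frame of per-segment statistics (columns `subject`,
#'   `level`, `mean_au`, `sd_au`, `range_au`, `t2_mi_percent`).
#' @param pairs Matched pairs from [matchControls()].
#' @param parameters Which stat columns to compare.
#' @return Data frame: `parameter`, `stratum`, `n_pairs`, medians/IQRs per
#'   group, `p_value`.
#' @export
compareGroups <- function(segStats, pairs,
                          parameters = c("mean_au", "sd_au", "range_au",
                                         "t2_mi_percent")) {
  if (nrow(pairs) == 0L)
    .cordError("inputError", "no matched pairs to compare")
  key <- function(subj, lev) paste(subj, lev, sep = "|")
  segStats$.key <- key(segStats$subject, segStats$level)
  caseRows <- match(key(pairs$case_subject, pairs$level), segStats$.key)
  ctrlRows <- match(key(pairs$control_subject, pairs$level), segStats$.key)
  if (anyNA(caseRows) || anyNA(ctrlRows))
    .cordError("inputError", "pairs reference segments missing from segStats")
  strata <- c("All", sort(unique(pairs$level)))
  out <- list()
  for (p in parameters) {
    for (st in strata) {
      sel <- if (st == "All") rep(TRUE, nrow(pairs)) else pairs$level == st
      xs <- segStats[[p]][caseRows[sel]]   # T2-positive
      ys <- segStats[[p]][ctrlRows[sel]]   # matched T2-negative
      mw <- if (length(xs) >= 1 && length(ys) >= 1) mannWhitneyU(xs, ys)
      sx <- summarizeMedianIQR(xs); sy <- summarizeMedianIQR(ys)
      out[[length(out) + 1L]] <- data.frame(
        parameter = p, stratum = st, n_pairs = sum(sel),
        negative_median = sy$median, negative_iqr = sy$iqr,
        positive_median = sx$median, positive_iqr = sx$iqr,
        p_value = mw$p.value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.stage <- function(name, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (inherits(e, "cordT2Error"))
      stop(errorCondition(sprintf("stage '%s': %s", name,
                                  conditionMessage(e)), class = class(e)))
  })
}

#' Run the full synthetic-cohort study replica
#'
#' Orchestrates phantom generation, per-subject quantification, simulated
#' subjective categorization with majority consensus, agreement statistics,
#' age- and level-matched control construction, group comparison, and ROC
#' analysis with Youden and closest-to-top-left cutoffs for the three
#' variability parameters (SD, range, T2-MI) and the absolute mean T2-SI.
#' Cervical levels without any consensus-positive segment are dropped from
#' the per-level strata (C2/3 carries no lesions by design). The run is
#' bit-reproducible for a fixed configuration.
#'
#' @param config A [cohortConfig()].
#' @param outputDir Optional directory; when given, all reports are written
#'   as CSV/JSON (a `FAILED` marker file is left behind if a stage aborts).
#' @param segmentation `"truth"` (use the phantom's ground-truth mask) or
#'   `"classical"` (re-segment each phantom with
#'   [segmentPhantomClassical()]).
#' @return List with elements `design`, `segments` (per-segment stats with
#'   truth and consensus labels), `agreement`, `pairs`, `comparison`, `roc`
#'   (named list of [RocResult-class]), `cutoffs` (data frame), `dice`
#'   (per-subject Dice vs truth when `segmentation = "classical"`, else
#'   NULL) and `manifest`.
#' @examples
#' \donttest{
#' res <- runCohort(cohortConfig(nCases = 4, nControls = 4, seed = 11,
#'                               dim = c(32L, 32L, 72L)))
#' res$agreement$percent_agreement
#' auc(res$roc$t2_mi_percent)
#' }
#' @export
runCohort <- function(config, outputDir = NULL,
                      segmentation = c("truth", "classical")) {
  stopifnot(inherits(config, "cordCohortConfig"))
  segmentation <- match.arg(segmentation)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    failMarker <- file.path(outputDir, "FAILED")
    on.exit(if (!is.null(failMarker) && !file.exists(file.path(outputDir, "manifest.json")))
      writeLines("run aborted; partial outputs retained", failMarker))
  }

  design <- .stage("simulate", simulateCohort(config))

  segments <- .stage("quantify", {
    rows <- lapply(seq_len(nrow(design)), function(i) {
      ph <- generatePhantom(design$spec[[i]])
      mask <- ph$mask
      dice <- NA_real_
      if (segmentation == "classical") {
        mask <- segmentPhantomClassical(ph$volume, config$cordRadius)
        dice <- diceCoefficient(mask, ph$mask)
      }
      st <- quantifySubject(ph$volume, mask, ph$landmarks, design$subject[i],
                            config$sdDenominator)
      st$cohort <- design$cohort[i]
      st$age <- design$age[i]
      st$sex <- design$sex[i]
      st$truth <- as.integer(!is.na(design$lesion_level[i]) &
                               st$level == design$lesion_level[i])
      st$dice <- dice
      st
    })
    do.call(rbind, rows)
  })

  agreement <- .stage("agree", {
    rt <- .withSeed(config$seed + 1L,
                    simulateRatings(segments$truth, config$nRaters,
                                    config$raterError))
    segments$consensus <- consensusRatings(rt)
    list(percent_agreement = percentAgreement(rt),
         fleiss_kappa = fleissKappa(rt),
         n_segments = nSegments(rt), n_raters = nRaters(rt))
  })

  pairs <- .stage("match", {
    cases <- segments[segments$consensus == 1L &
                        segments$cohort == "patient", ]
    pool <- segments[segments$consensus == 0L &
                       segments$cohort == "volunteer", ]
    matchControls(cases[, c("subject", "level", "age")],
                  pool[, c("subject", "level", "age")])
  })

  comparison <- if (nrow(pairs) == 0L) NULL else
    .stage("compare", compareGroups(segments, pairs))

  rocs <- .stage("roc", {
    key <- paste(segments$subject, segments$level, sep = "|")
    ci <- match(paste(pairs$case_subject, pairs$level, sep = "|"), key)
    ni <- match(paste(pairs$control_subject, pairs$level, sep = "|"), key)
    labels <- rep(c(1L, 0L), c(length(ci), length(ni)))
    lapply(stats::setNames(nm = c("sd_au", "range_au", "t2_mi_percent")),
           function(p) rocAnalysis(segments[[p]][c(ci, ni)], labels))
  })

  cutoffs <- do.call(rbind, lapply(names(rocs), function(p) {
    yc <- youdenCutoffs(rocs[[p]])
    tl <- closestTopLeftCutoff(rocs[[p]])
    rbind(data.frame(parameter = p, method = "youden", yc[1:3],
                     stringsAsFactors = FALSE),
          data.frame(parameter = p, method = "top_left", tl[1:3],
                     stringsAsFactors = FALSE))
  }))

  manifest <- list(
    package = "cordT2",
    version = as.character(utils::packageVersion("cordT2")),
    seed = config$seed,
    segmentation = segmentation,
    config = unclass(config),
    config_md5 = .configHash(config)
  )

  res <- list(design = design, segments = segments, agreement = agreement,
              pairs = pairs, comparison = comparison, roc = rocs,
              cutoffs = cutoffs,
              dice = if (segmentation == "classical")
                unique(segments[, c("subject", "dice")]) else NULL,
              manifest = manifest)

  if (!is.null(outputDir)) {
    w <- function(df, f) utils::write.csv(df, file.path(outputDir, f),
                                          row.names = FALSE, quote = FALSE)
    w(segments[, setdiff(names(segments), "dice")], "segments.csv")
    w(pairs, "pairs.csv")
    if (!is.null(comparison)) w(comparison, "comparison.csv")
    w(cutoffs, "cutoffs.csv")
    for (p in names(rocs))
      w(as.data.frame(rocs[[p]]), sprintf("roc_%s.csv", p))
    jsonlite::write_json(agreement, file.path(outputDir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    failMarker <- NULL
  }
  res
}

.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA),
             tf)
  unname(tools::md5sum(tf))
}
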