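#' Landmark x gender x slice-count sweep
#'
#' For every gender stratum, landmark and slice count, fits the
#' through-origin scaling factor on that stratum, predicts every subject's
#' total VAT volume from their landmark area via \code{V = A ST / f}, and
#' summarises agreement (Bland-Altman bias and sigma).  Evaluation is
#' in-sample by default -- f is fitted and assessed on the same stratum;
#' \code{looMode = TRUE} instead predicts each subject from a fit on the
#' remaining subjects (leave-one-out) for an out-of-sample error.
#'
#' @param cohort cohort data frame (see [generateCohort()]).
#' @param landmarks character vector of landmark names to sweep; default
#'   is every landmark with area columns in the cohort.
#' @param stCm effective slice thickness in cm; defaults to the cohort's
#'   \code{stCm} attribute.
#' @param nSlicesSet slice counts to sweep, subset of \code{c(1, 5)}.
#' @param genders strata to sweep; default the genders present.
#' @param looMode logical: leave-one-out evaluation instead of in-sample.
#' @return A data frame with one row per (gender, landmark, n_slices):
#'   columns \code{gender}, \code{landmark}, \code{n_slices}, \code{f},
#'   \code{r_squared} (partial-on-total orientation),
#'   \code{r_squared_volume_on_area}, \code{bias_ml}, \code{sigma_ml},
#'   \code{n}, \code{flagged}.  Strata with fewer than 3 subjects are
#'   flagged and their statistics suppressed.
#' @export
landmarkSweep <- function(cohort, landmarks = NULL, stCm = NULL,
                          nSlicesSet = c(1L, 5L), genders = NULL,
                          looMode = FALSE) {
  if (is.null(stCm)) stCm <- attr(cohort, "stCm")
  if (is.null(stCm)) stop("'stCm' not given and cohort carries no stCm attribute")
  if (is.null(landmarks)) {
    landmarks <- sub("^a1_", "", grep("^a1_", names(cohort), value = TRUE))
    landmarks <- intersect(LANDMARK_ORDER, landmarks)  # canonical order
  }
  if (is.null(genders)) genders <- sort(unique(cohort$gender))
  rows <- list()
  for (g in genders) {
    strat <- cohort[cohort$gender == g, , drop = FALSE]
    for (lm in landmarks) {
      for (ns in as.integer(nSlicesSet)) {
        col <- sprintf("a%d_%s", ns, lm)
        if (!col %in% names(strat))
          stop("cohort lacks column '", col, "'")
        nSub <- sum(is.finite(strat[[col]]) & is.finite(strat$v_vat_t_ml))
        if (nSub < 3L) {
          rows[[length(rows) + 1L]] <- data.frame(
            gender = g, landmark = lm, n_slices = ns,
            f = NA_real_, r_squared = NA_real_,
            r_squared_volume_on_area = NA_real_,
            bias_ml = NA_real_, sigma_ml = NA_real_,
            n = nSub, flagged = TRUE, stringsAsFactors = FALSE)
          next
        }
        fit <- fitScalingFactor(strat, lm, ns, stCm)
        pred <- if (looMode) {
          vapply(seq_len(nrow(strat)), function(i) {
            fi <- fitScalingFactor(strat[-i, , drop = FALSE], lm, ns, stCm)
            predictVolume(strat[[col]][i], stCm, fi@f)
          }, numeric(1))
        } else {
          predictVolume(strat[[col]], stCm, fit@f)
        }
        ba <- blandAltman(strat$v_vat_t_ml, pred)
        rows[[length(rows) + 1L]] <- data.frame(
          gender = g, landmark = lm, n_slices = ns,
          f = fit@f, r_squared = fit@rSquared,
          r_squared_volume_on_area = fit@rSquaredVolumeOnArea,
          bias_ml = ba@bias, sigma_ml = ba@sigma,
          n = nSub, flagged = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Split a gender stratum into age tertiles
#'
#' Sorts the stratum by age (ties broken by id for determinism) and cuts
#' it into three nearly equally sized subgroups; sizes differ by at most
#' one.  With \code{convention = "middle"} (default) an odd remainder goes
#' to the middle group -- reproducing the 31/32/31 female split of a
#' 94-subject stratum -- whereas \code{"earliest"} assigns extras to the
#' earliest groups (32/31/31).  A 36-subject stratum yields 12/12/12
#' either way.
#'
#' @param cohort cohort data frame with \code{gender} and \code{age}.
#' @param gender stratum to split (\code{"F"} or \code{"M"}).
#' @param convention where remainder subjects go: \code{"middle"} or
#'   \code{"earliest"}.
#' @return A list with \code{groups} (list of three data frames, youngest
#'   first), \code{sizes}, and \code{cutAges} (max age of groups I and II).
#' @export
ageTertiles <- function(cohort, gender, convention = c("middle", "earliest")) {
  convention <- match.arg(convention)
  strat <- cohort[cohort$gender == gender, , drop = FALSE]
  n <- nrow(strat)
  if (n < 3L) stop("need at least 3 subjects of gender '", gender, "'")
  strat <- strat[order(strat$age, strat$id), , drop = FALSE]
  base <- n %/% 3L
  r <- n %% 3L
  extra <- switch(convention,
    middle   = c(if (r >= 2L) 1L else 0L, if (r >= 1L) 1L else 0L, 0L),
    earliest = c(if (r >= 1L) 1L else 0L, if (r >= 2L) 1L else 0L, 0L))
  sizes <- base + extra
  idx <- cumsum(sizes)
  groups <- list(strat[seq_len(idx[1]), , drop = FALSE],
                 strat[(idx[1] + 1L):idx[2], , drop = FALSE],
                 strat[(idx[2] + 1L):idx[3], , drop = FALSE])
  list(groups = groups,
       sizes = sizes,
       cutAges = c(max(groups[[1]]$age), max(groups[[2]]$age)))
}

#' Best landmark by agreement
#'
#' Among the unflagged sweep rows of one gender and slice count, returns
#' the landmark with the smallest Bland-Altman sigma; exact ties break
#' toward the more caudal landmark.
#'
#' @param rows a sweep table from [landmarkSweep()].
#' @param gender stratum of interest.
#' @param nSlices 1 or 5.
#' @return Landmark name (character scalar).
#' @export
bestLandmark <- function(rows, gender, nSlices) {
  sub <- rows[rows$gender == gender & rows$n_slices == nSlices &
                !rows$flagged & is.finite(rows$sigma_ml), , drop = FALSE]
  if (nrow(sub) == 0L) stop("no usable sweep rows for this stratum")
  ord <- order(sub$sigma_ml, match(sub$landmark, LANDMARK_ORDER))
  sub$landmark[ord[1L]]
}

#' Sweep within age tertiles
#'
#' Runs [landmarkSweep()] separately inside each age tertile of a gender
#' stratum, for subgroup-level agreement tables.
#'
#' @inheritParams ageTertiles
#' @inheritParams landmarkSweep
#' @return A data frame of sweep rows with an extra \code{age_group}
#'   column (\code{"I"}, \code{"II"}, \code{"III"}).
#' @export
tertileSweep <- function(cohort, gender, landmarks = NULL, stCm = NULL,
                         nSlicesSet = c(1L, 5L),
                         convention = c("middle", "earliest")) {
  if (is.null(stCm)) stCm <- attr(cohort, "stCm")
  tert <- ageTertiles(cohort, gender, convention)
  out <- lapply(seq_along(tert$groups), function(i) {
    sw <- landmarkSweep(tert$groups[[i]], landmarks = landmarks,
                        stCm = stCm, nSlicesSet = nSlicesSet,
                        genders = gender)
    sw$age_group <- c("I", "II", "III")[i]
    sw
  })
  do.call(rbind, out)
}
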