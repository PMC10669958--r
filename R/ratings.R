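# Rating-table model: the five-point confidence scores of each observer on
# each tooth surface, their binarization, consensus ground truth with
# adjudication of conflicts, and the per-observer report tables.
#
# A rating table is a plain data.frame with the fixed column set
#   case_id, tooth_fdi, surface, condition, observer_id, arm, score, session
# (surface in {mesial, distal}; arm in {unaided, aided}; score 1..5; session
# 1 for the main read, 2 for the repeat read used for intra-observer
# agreement).

.RATING_COLS <- c("case_id", "tooth_fdi", "surface", "condition", "observer_id",
                  "arm", "score", "session")

.surfaceKey <- function(df) paste(df$case_id, df$tooth_fdi, df$surface, sep = "|")

#' Validate a rating table
#'
#' Checks the fixed column set, legal factor levels, the 1..5 score range and
#' uniqueness of (case, tooth, surface, observer, arm, session).
#'
#' @param table a data.frame of rating records
#' @return the table, invisibly; stops with an informative message otherwise
#' @export
validateRatingTable <- function(table) {
  miss <- setdiff(.RATING_COLS, names(table))
  if (length(miss)) stop("rating table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(table$surface %in% c("mesial", "distal")))
    stop("surface must be 'mesial' or 'distal'")
  if (!all(table$arm %in% c("unaided", "aided")))
    stop("arm must be 'unaided' or 'aided'")
  if (!all(table$condition %in% .TOOTH_CONDITIONS))
    stop("condition must be one of: ", paste(.TOOTH_CONDITIONS, collapse = ", "))
  if (!all(table$score %in% 1:5)) stop("score must be an integer in 1..5")
  key <- paste(.surfaceKey(table), table$observer_id, table$arm, table$session)
  if (anyDuplicated(key))
    stop("duplicate records for the same (case, tooth, surface, observer, arm, session)")
  invisible(table)
}

#' Binarize five-point confidence scores
#'
#' Scores 1-3 map to "absence", scores 4-5 to "presence".
#'
#' @param score integer vector of scores in 1..5
#' @return character vector of "absence"/"presence"
#' @export
binarizeScore <- function(score) {
  if (any(!score %in% 1:5)) stop("score out of range 1..5")
  ifelse(score >= 4, "presence", "absence")
}

#' Remove surfaces of missing or excluded teeth
#'
#' A surface leaves the analysis when any observer recorded the tooth as
#' "missing" or "excluded" in any arm; restored and bridge-support teeth keep
#' their surface scores.  Drops are reported via message.
#'
#' @param table a rating table
#' @return the cleaned table
#' @export
cleanRatings <- function(table) {
  validateRatingTable(table)
  bad <- unique(.surfaceKey(table)[table$condition %in% c("missing", "excluded")])
  if (length(bad))
    message(sprintf("cleaning: dropping %d surfaces of missing/excluded teeth", length(bad)))
  table[!(.surfaceKey(table) %in% bad), , drop = FALSE]
}

#' Consensus ground truth from unanimous binarized scores
#'
#' A surface becomes ground truth when every observer's binarized score in the
#' chosen arm agrees (provenance "unanimous"); otherwise it enters the conflict
#' list (reason "disagreement", or "incomplete" when an observer's score is
#' missing).
#'
#' @param table a cleaned rating table
#' @param arm which arm's scores feed the consensus ("unaided" or "aided")
#' @param session main-read session id (default 1)
#' @return list with \code{groundTruth} (case_id, tooth_fdi, surface, label,
#'   provenance) and \code{conflicts} (case_id, tooth_fdi, surface, reason)
#' @export
consensusGroundTruth <- function(table, arm = c("unaided", "aided"), session = 1L) {
  arm <- match.arg(arm)
  validateRatingTable(table)
  observers <- sort(unique(table$observer_id))
  sub <- table[table$arm == arm & table$session == session, , drop = FALSE]
  allSurf <- unique(table[, c("case_id", "tooth_fdi", "surface")])
  key <- .surfaceKey(allSurf)
  subKey <- .surfaceKey(sub)
  lab <- binarizeScore(sub$score)
  grp <- split(seq_len(nrow(sub)), factor(subKey, levels = key))
  status <- vapply(grp, function(rows) {
    if (length(rows) < length(observers) ||
        !setequal(sub$observer_id[rows], observers)) return("incomplete")
    if (length(unique(lab[rows])) == 1L) lab[rows[1]] else "disagreement"
  }, character(1))
  status <- status[key]   # align with allSurf order
  isGt <- status %in% c("absence", "presence")
  gt <- cbind(allSurf[isGt, , drop = FALSE], label = status[isGt],
              provenance = rep("unanimous", sum(isGt)))
  cf <- cbind(allSurf[!isGt, , drop = FALSE], reason = status[!isGt])
  rownames(gt) <- rownames(cf) <- NULL
  list(groundTruth = gt, conflicts = cf)
}

#' Merge adjudication decisions into a partial ground truth
#'
#' Conflicting surfaces resolved in adjudication sessions are appended with
#' provenance "adjudicated".  Every conflict must be covered; decisions for
#' surfaces that already have a unanimous label are ignored with a warning
#' (unanimity wins).
#'
#' @param groundTruth,conflicts the two components from [consensusGroundTruth()]
#' @param decisions data.frame with case_id, tooth_fdi, surface, label
#' @return the completed ground-truth table
#' @export
mergeAdjudication <- function(groundTruth, conflicts, decisions) {
  need <- c("case_id", "tooth_fdi", "surface", "label")
  miss <- setdiff(need, names(decisions))
  if (length(miss)) stop("decisions lack columns: ", paste(miss, collapse = ", "))
  if (!all(decisions$label %in% c("absence", "presence")))
    stop("decision labels must be 'absence' or 'presence'")
  dKey <- .surfaceKey(decisions)
  cKey <- .surfaceKey(conflicts)
  gKey <- .surfaceKey(groundTruth)
  uncovered <- setdiff(cKey, dKey)
  if (length(uncovered))
    stop("adjudication does not cover all conflicts: ",
         paste(utils::head(uncovered, 10), collapse = "; "))
  extraneous <- dKey %in% gKey
  if (any(extraneous))
    warning(sprintf("%d decision(s) for non-conflict surfaces ignored (unanimity wins)",
                    sum(extraneous)))
  use <- decisions[dKey %in% cKey, need, drop = FALSE]
  use <- use[!duplicated(.surfaceKey(use)), , drop = FALSE]
  adj <- cbind(use, provenance = rep("adjudicated", nrow(use)))
  out <- rbind(groundTruth[, c(need, "provenance")], adj)
  rownames(out) <- NULL
  out
}

#' Confusion counts of one observer against the ground truth
#'
#' Binarizes the observer's scores in the given arm and counts TP/FP/TN/FN
#' against the ground-truth labels over all surfaces present in the ground
#' truth ("presence" is the positive class).
#'
#' @param table a cleaned rating table
#' @param groundTruth a complete ground-truth table
#' @param observerId,arm the observer and arm to evaluate
#' @param session main-read session id (default 1)
#' @return a [ConfusionCounts-class]
#' @export
confusionFromRatings <- function(table, groundTruth, observerId,
                                 arm = c("unaided", "aided"), session = 1L) {
  arm <- match.arg(arm)
  sub <- table[table$observer_id == observerId & table$arm == arm &
               table$session == session, , drop = FALSE]
  gtLab <- groundTruth$label[match(.surfaceKey(sub), .surfaceKey(groundTruth))]
  keep <- !is.na(gtLab)
  call <- binarizeScore(sub$score[keep]) == "presence"
  truth <- gtLab[keep] == "presence"
  confusionCounts(TP = sum(call & truth), FP = sum(call & !truth),
                  TN = sum(!call & !truth), FN = sum(!call & truth))
}

#' Intra-observer repeatability from repeat-session ratings
#'
#' Pairs each observer's main read (session 1) with the repeat read (session 2)
#' on the repeat subset and computes Cohen's and weighted kappa on the
#' five-point and binary scales, per observer and arm.  Surfaces lacking either
#' session are excluded with a warning.
#'
#' @param table a rating table containing session-2 records
#' @param subsetCases optional case ids restricting the repeat subset
#' @return data.frame, one row per observer x arm, with kappa columns and the
#'   number of pairs used
#' @export
intraObserver <- function(table, subsetCases = NULL) {
  validateRatingTable(table)
  if (!is.null(subsetCases)) {
    if (!length(subsetCases)) stop("empty repeat subset")
    table <- table[table$case_id %in% subsetCases, , drop = FALSE]
  }
  if (!any(table$session == 2L)) stop("no repeat-session (session 2) records")
  out <- list()
  dropped <- 0L
  for (obs in sort(unique(table$observer_id))) {
    for (arm in c("unaided", "aided")) {
      s1 <- table[table$observer_id == obs & table$arm == arm & table$session == 1L, ]
      s2 <- table[table$observer_id == obs & table$arm == arm & table$session == 2L, ]
      if (!nrow(s2)) next
      m <- match(.surfaceKey(s2), .surfaceKey(s1))
      dropped <- dropped + sum(is.na(m))
      ok <- !is.na(m)
      a <- s1$score[m[ok]]; b <- s2$score[ok]
      out[[length(out) + 1L]] <- data.frame(
        observer_id = obs, arm = arm, nPairs = length(a),
        cohenFive = cohensKappa(a, b, categories = 1:5),
        cohenBinary = cohensKappa(binarizeScore(a), binarizeScore(b),
                                  categories = c("absence", "presence")),
        weightedFiveLinear = weightedKappa(a, b, "linear", categories = 1:5),
        weightedFiveQuadratic = weightedKappa(a, b, "quadratic", categories = 1:5),
        weightedBinary = weightedKappa(binarizeScore(a), binarizeScore(b),
                                       "quadratic", categories = c("absence", "presence")))
    }
  }
  if (dropped > 0L) warning(sprintf("%d unmatched repeat pairs excluded", dropped))
  if (!length(out)) stop("no paired repeat records found")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# n x k count matrix of observers' (binarized or raw) scores per surface
.fleissCounts <- function(table, arm, scale = c("binary", "five"), session = 1L) {
  scale <- match.arg(scale)
  sub <- table[table$arm == arm & table$session == session, , drop = FALSE]
  key <- .surfaceKey(sub)
  vals <- if (scale == "binary") binarizeScore(sub$score) else as.character(sub$score)
  lev <- if (scale == "binary") c("absence", "presence") else as.character(1:5)
  tab <- table(factor(key), factor(vals, levels = lev))
  m <- rowSums(tab)
  full <- m == max(m)
  matrix(tab[full, , drop = FALSE], ncol = length(lev),
         dimnames = list(NULL, lev))
}

#' Full reader-study report
#'
#' Produces the complete evaluation bundle: per-observer x arm binarized
#' score distributions, confusion counts with sensitivity / specificity /
#' accuracy and Cohen's kappa against the ground truth, AUCs from the ordinal
#' scores, Fleiss kappa (overall and per category, binary and five-point
#' scales) per arm, and pairwise inter-observer agreement per arm.
#'
#' @param table a cleaned rating table
#' @param groundTruth a complete ground-truth table
#' @param session main-read session id (default 1)
#' @return list of data.frames: \code{distribution}, \code{performance},
#'   \code{fleiss}, \code{pairwise}, plus \code{groundTruthCounts}
#' @export
fullReport <- function(table, groundTruth, session = 1L) {
  validateRatingTable(table)
  observers <- sort(unique(table$observer_id))
  arms <- c("unaided", "aided")
  dist <- list(); perf <- list()
  for (obs in observers) for (arm in arms) {
    sub <- table[table$observer_id == obs & table$arm == arm &
                 table$session == session, , drop = FALSE]
    if (!nrow(sub)) next
    b <- binarizeScore(sub$score)
    dist[[length(dist) + 1L]] <- data.frame(
      observer_id = obs, arm = arm,
      absence = sum(b == "absence"), presence = sum(b == "presence"))
    cc <- confusionFromRatings(table, groundTruth, obs, arm, session)
    met <- classificationMetrics(cc)
    gtLab <- groundTruth$label[match(.surfaceKey(sub), .surfaceKey(groundTruth))]
    ok <- !is.na(gtLab)
    auc <- rocAuc(sub$score[ok], gtLab[ok] == "presence")$auc
    perf[[length(perf) + 1L]] <- data.frame(
      observer_id = obs, arm = arm, TP = cc@TP, TN = cc@TN, FP = cc@FP, FN = cc@FN,
      sensitivity = met[["sensitivity"]], specificity = met[["specificity"]],
      accuracy = met[["accuracy"]], kappa = cohensKappa(cc), auc = auc)
  }
  fl <- list()
  for (arm in arms) for (scale in c("binary", "five")) {
    cnt <- .fleissCounts(table, arm, scale, session)
    if (!nrow(cnt)) next
    fk <- fleissKappa(cnt)
    fl[[length(fl) + 1L]] <- data.frame(
      arm = arm, scale = scale,
      category = c(colnames(cnt), "overall"),
      kappa = c(fk$perCategory, fk$overall))
  }
  pw <- list()
  if (length(observers) >= 2L) {
    prs <- utils::combn(observers, 2)
    for (c_ in seq_len(ncol(prs))) for (arm in arms) {
      o1 <- table[table$observer_id == prs[1, c_] & table$arm == arm &
                  table$session == session, ]
      o2 <- table[table$observer_id == prs[2, c_] & table$arm == arm &
                  table$session == session, ]
      m <- match(.surfaceKey(o1), .surfaceKey(o2))
      ok <- !is.na(m)
      a <- o1$score[ok]; b <- o2$score[m[ok]]
      pw[[length(pw) + 1L]] <- data.frame(
        observer_a = prs[1, c_], observer_b = prs[2, c_], arm = arm,
        weightedFiveQuadratic = weightedKappa(a, b, "quadratic", categories = 1:5),
        cohenFive = cohensKappa(a, b, categories = 1:5),
        cohenBinary = cohensKappa(binarizeScore(a), binarizeScore(b),
                                  categories = c("absence", "presence")))
    }
  }
  gtc <- data.frame(absence = sum(groundTruth$label == "absence"),
                    presence = sum(groundTruth$label == "presence"))
  list(distribution = do.call(rbind, dist), performance = do.call(rbind, perf),
       fleiss = if (length(fl)) do.call(rbind, fl) else NULL,
       pairwise = if (length(pw)) do.call(rbind, pw) else NULL,
       groundTruthCounts = gtc)
}

#' Serialise a report bundle to CSV + JSON
#'
#' @param report the list from [fullReport()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeReportBundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report)) {
    x <- report[[nm]]
    if (is.data.frame(x))
      utils::write.csv(x, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(dir, "report.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "rows")
  invisible(dir)
}
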