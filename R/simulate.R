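## End-to-end validation harness: simulated cross-link outcomes from a ground
## truth, fold labelling at contact-fraction thresholds, ROC/AUC analysis.

## Append an external structure (e.g. the ground truth) to an ensemble by
## matching its SSEs against the consensus intervals.
appendModel <- function(ensemble, model) {
  cs <- ensemble@commonSses
  row <- matrix(NA_integer_, nrow = 1L, ncol = nrow(cs) * 2L)
  dim(row) <- c(1L, nrow(cs), 2L)
  used <- integer(0)
  for (ci in seq_len(nrow(cs))) {
    best <- 0; bestK <- NA_integer_
    for (k in seq_len(nrow(model@sses))) {
      if (model@sses$kind[k] != cs$kind[ci] || k %in% used) next
      j <- intervalJaccard(model@sses$start[k], model@sses$end[k], cs$start[ci], cs$end[ci])
      if (j >= ensemble@overlapFraction && j > best) { best <- j; bestK <- k }
    }
    if (!is.na(bestK)) {
      used <- c(used, bestK)
      row[1L, ci, ] <- c(model@sses$start[bestK], model@sses$end[bestK])
    }
  }
  if (sum(!is.na(row[1L, , 1L])) < 2L)
    stop("structure ", model@modelId, " does not share the ensemble's common SSEs")
  out <- ensemble
  out@models <- c(ensemble@models, model)
  m2 <- array(NA_integer_, dim = c(length(out@models), nrow(cs), 2L))
  m2[seq_len(length(ensemble@models)), , ] <- ensemble@matched
  m2[length(out@models), , ] <- row
  out@matched <- m2
  out
}

#' Simulate cross-link outcomes from a ground-truth structure
#'
#' Each planned residue pair forms a disulfide in the simulation when its
#' C-beta-C-beta distance in the ground truth is below \code{threshold}
#' (9 Angstrom by default — deliberately stricter than the 19 Angstrom
#' cross-linkable planning window). Planned residues missing from the truth
#' yield outcome 0 with a warning. Per-pair outcome vectors are then
#' interpreted into SSE contact states via [interpretXlinkData()].
#'
#' @param truth a \linkS4class{StructuralModel}.
#' @param plans named list of \linkS4class{CrossLinkPlan}.
#' @param threshold disulfide formation distance in Angstrom (default 9).
#' @return list with \code{Y} (named list of outcome vectors), \code{X}
#'   (named contact-state vector per SSE pair), \code{ties} (named logical).
#' @export
simulateOutcomes <- function(truth, plans, threshold = 9.0) {
  Y <- list(); X <- integer(0); ties <- logical(0)
  for (nm in names(plans)) {
    plan <- plans[[nm]]
    y <- integer(nrow(plan@links))
    for (r in seq_len(nrow(plan@links))) {
      i <- plan@links[r, 1L]; j <- plan@links[r, 2L]
      if (!(i %in% truth@resno) || !(j %in% truth@resno)) {
        warning("truth lacks residue ", if (i %in% truth@resno) j else i,
                "; outcome set to 0 for link ", i, "-", j)
        y[r] <- 0L
      } else {
        y[r] <- as.integer(cbDistance(truth, i, j) < threshold)
      }
    }
    dec <- interpretXlinkData(y, plan)
    Y[[nm]] <- y
    X[nm] <- dec$contact
    ties[nm] <- dec$tie
  }
  list(Y = Y, X = X, ties = ties)
}

#' Label models as correct-fold or not against a ground truth
#'
#' For each contact-fraction threshold r, contact graphs of all models and the
#' truth are recomputed with \code{minResidueFraction = r} and a model is
#' labelled correct when its full-universe fold signature equals the truth's.
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param truth a \linkS4class{StructuralModel} sharing the common SSE set.
#' @param rValues contact-fraction thresholds (default c(0.05, 0.1, 0.15, 0.2)).
#' @param minContacts,contactDistance contact criteria (defaults 5 and 9).
#' @return logical matrix, models x rValues.
#' @export
labelModels <- function(ensemble, truth, rValues = c(0.05, 0.1, 0.15, 0.2),
                        minContacts = 5L, contactDistance = 9.0) {
  aug <- appendModel(ensemble, truth)
  nM <- length(ensemble@models)
  univ <- ssePairUniverse(aug)
  out <- matrix(NA, nrow = nM, ncol = length(rValues),
                dimnames = list(vapply(ensemble@models, modelId, character(1)),
                                as.character(rValues)))
  for (k in seq_along(rValues)) {
    gs <- buildContactGraphs(aug, minContacts = minContacts,
                             minResidueFraction = rValues[k],
                             contactDistance = contactDistance)
    sig <- signatureMatrix(gs, univ)
    truthSig <- sig[nM + 1L, ]
    out[, k] <- apply(sig[seq_len(nM), , drop = FALSE], 1L,
                      function(s) all(s == truthSig))
  }
  out
}

#' ROC analysis of fold-level likelihoods against fold labels
#'
#' Ranks models by likelihood and computes the ROC curve and trapezoidal AUC
#' (midrank handling of ties), the probability that a randomly chosen
#' correct-fold model outranks a randomly chosen wrong-fold one.
#'
#' @param likelihoods per-model scores (higher = more likely correct).
#' @param labels per-model logical (TRUE = correct fold).
#' @return list with \code{auc} (NA when labels are degenerate), \code{points}
#'   (data.frame fpr/tpr, NULL when degenerate), \code{note}.
#' @export
rocAnalysis <- function(likelihoods, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    return(list(auc = NA_real_, points = NULL,
                note = "AUC undefined: need at least one positive and one negative label"))
  r <- pROC::roc(response = labels, predictor = as.numeric(likelihoods),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  list(auc = as.numeric(pROC::auc(r)), points = pts, note = "")
}

#' Run the full planning-and-simulation pipeline on a synthetic fixture
#'
#' Generates the fixture, builds contact graphs and the probability model,
#' selects and assesses the topological fingerprint, plans cross-links per
#' fingerprint pair under the configured noise model, simulates outcomes from
#' the ground truth, interprets them into a fold decision (including
#' none-of-the-above), labels the models against the truth at each r and runs
#' the ROC analysis.
#'
#' @param spec a [fixtureSpec()].
#' @param config a [defaultConfig()]-style list.
#' @param assessXlink also compute each plan's cross-link Bayes error
#'   (default FALSE; the fold-level assessment is always computed).
#' @return a SimulationReport: list with elements fixture, fingerprint,
#'   trajectory, plans, simulated (X/Y), likelihoods, decision, notaDetected,
#'   labels, roc (one entry per r), auc (named numeric per r).
#' @export
runEndToEnd <- function(spec, config = defaultConfig(), assessXlink = FALSE) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "': ", conditionMessage(e), call. = FALSE))
  }
  fx <- stage("generate_fixture", generateFixture(spec))
  ens <- fx$ensemble
  graphs <- stage("topology", buildContactGraphs(
    ens, minContacts = config$minContacts,
    minResidueFraction = config$minResidueFraction,
    contactDistance = config$contactDistance))
  pm <- stage("fingerprint", estimateContactProbs(graphs, q = config$q))
  fp <- stage("fingerprint", selectFingerprint(pm, stopThreshold = config$stopThreshold,
                                               maxPairs = config$maxPairs))
  if (nrow(fp@pairs) == 0L) stop("stage 'fingerprint': empty fingerprint")
  fp <- stage("fingerprint", assessFingerprint(fp, graphs, q = config$q))
  noise <- stage("crosslink", makeNoiseModel(
    ens, deltaMax = config$deltaMax, decay = config$decay,
    nBackbones = config$nBackbones, amplitudeMax = config$amplitudeMax,
    enmCutoff = config$enmCutoff))
  plans <- stage("crosslink", planCrossLinks(
    ens, fp, graphs, probModel = pm, noise = noise,
    tiers = linkProbTiers(config$pNear, config$pMid, config$pFar),
    planSize = config$planSize, k0 = config$k0, q = config$q,
    maxDistance = config$xlinkMaxDistance, assess = assessXlink))
  if (length(plans) == 0L) stop("stage 'crosslink': no SSE pair could be planned")
  sim <- stage("simulate_outcomes", simulateOutcomes(fx$truth, plans,
                                                     threshold = config$simDistance))
  plannedPairs <- do.call(rbind, lapply(plans, function(p) p@ssePair))
  sig <- signatureMatrix(graphs, plannedPairs)
  ids <- vapply(ens@models, modelId, character(1))
  decision <- stage("interpret", interpretFoldData(unname(sim$X), sig, q = config$q,
                                                   modelIds = ids))
  labels <- stage("label_models", labelModels(
    ens, fx$truth, rValues = config$rValues, minContacts = config$minContacts,
    contactDistance = config$contactDistance))
  roc <- lapply(seq_along(config$rValues), function(k)
    stage("roc", rocAnalysis(decision$likelihoods, labels[, k])))
  names(roc) <- as.character(config$rValues)
  list(fixture = fx, fingerprint = fp, plans = plans, simulated = sim,
       likelihoods = decision$likelihoods, decision = decision,
       notaDetected = decision$noneOfTheAbove, labels = labels, roc = roc,
       auc = vapply(roc, function(x) x$auc, numeric(1)))
}

#' Count models whose geometry agrees with observed cross-link outcomes
#'
#' A model agrees with an outcome y for link (i, j) when some per-SSE register
#' offset within \code{deltaMax} makes its C-beta distance consistent with the
#' observation (closer than \code{threshold} for y = 1, at least
#' \code{threshold} for y = 0; residues absent under the shift only satisfy
#' y = 0). A model agrees overall when it agrees on every link of every plan —
#' the misalignment-robustness analysis: allowing small offsets lets register-
#' shifted models of the correct fold match the data.
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param plans named list of \linkS4class{CrossLinkPlan}.
#' @param Y named list of outcome vectors (as from [simulateOutcomes()]).
#' @param deltaMax maximum per-SSE register offset to allow (default 0).
#' @param threshold disulfide distance criterion in Angstrom (default 9).
#' @return logical vector, one entry per model.
#' @export
countLinkAgreement <- function(ensemble, plans, Y, deltaMax = 0L, threshold = 9.0) {
  dvals <- seq.int(-deltaMax, deltaMax)
  vapply(ensemble@models, function(m) {
    for (nm in names(plans)) {
      links <- plans[[nm]]@links
      y <- Y[[nm]]
      for (r in seq_len(nrow(links))) {
        ok <- FALSE
        for (da in dvals) {
          for (db in dvals) {
            pi_ <- match(links[r, 1L] + da, m@resno)
            pj <- match(links[r, 2L] + db, m@resno)
            form <- if (is.na(pi_) || is.na(pj)) FALSE else
              vnorm(m@cb[pi_, ] - m@cb[pj, ]) < threshold
            if (form == (y[r] == 1L)) { ok <- TRUE; break }
          }
          if (ok) break
        }
        if (!ok) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
}

#' Write a simulation report as JSON-lines plus ROC point tables
#'
#' One JSON record per stage (fingerprint, plans, simulated data, decision,
#' labels, AUC) to \code{file}; ROC points per r threshold to tab-separated
#' files alongside it.
#'
#' @param report the list returned by [runEndToEnd()].
#' @param file output path for the JSON-lines report.
#' @export
writeSimulationReport <- function(report, file) {
  fp <- report$fingerprint
  recs <- list(
    list(stage = "fingerprint",
         pairs = pairLabel(fp@pairs[, 1L], fp@pairs[, 2L]),
         scores = fp@scores, epsilon = fp@epsilon, tau = fp@tieRatio,
         nu = fp@notaRatio),
    list(stage = "plans",
         pairs = names(report$plans),
         n_links = vapply(report$plans, function(p) nrow(p@links), integer(1)),
         epsilon_xlink = vapply(report$plans, function(p) p@epsilonXlink, numeric(1))),
    list(stage = "simulated", X = as.list(report$simulated$X)),
    list(stage = "decision", best_models = report$decision$bestModels,
         none_of_the_above = report$notaDetected),
    list(stage = "labels", per_r = apply(report$labels, 2L, sum)),
    list(stage = "roc", auc = as.list(report$auc)))
  con <- file(file, "w"); on.exit(close(con))
  for (rec in recs)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"), con)
  for (rn in names(report$roc)) {
    pts <- report$roc[[rn]]$points
    if (!is.null(pts))
      write.table(pts, paste0(file, ".roc_r", rn, ".tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
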