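#' Predict activity for designed candidate compounds
#'
#' Evaluates a linear activity model on candidate descriptor rows and
#' reports each prediction together with its improvement over the best
#' observed activity in the modeling set and, when modeling records are
#' supplied, an applicability-domain flag (leverage against the modeling
#' design below the warning leverage).
#'
#' @param model A `qsar_mlr` model, e.g. [reported_mlr_model()] or a
#'   [fit_mlr()] refit.
#' @param candidates Candidate records carrying all model descriptors.
#' @param modeling_records Optional modeling-set records; used for the
#'   improvement baseline (max observed pIC50) and the AD check. If `NULL`,
#'   `improvement_vs_best` and `in_domain` are `NA`.
#' @return A data frame of class `candidate_predictions`:
#'   `compound_id`, the model descriptors, `predicted_pIC50`,
#'   `improvement_vs_best`, `in_domain`.
#' @examples
#' ds <- load_study_dataset()
#' predict_candidates(reported_mlr_model(), ds$candidates, ds$modeling)
#' @export
predict_candidates <- function(model, candidates, modeling_records = NULL) {
  pred <- predict_mlr(model, candidates)
  if (any(!is.finite(pred))) stop("non-finite candidate prediction", call. = FALSE)

  out <- data.frame(compound_id = record_ids(candidates),
                    as.data.frame(candidates)[, model$terms, drop = FALSE],
                    predicted_pIC50 = pred,
                    stringsAsFactors = FALSE)
  if (!is.null(modeling_records)) {
    baseline <- max(modeling_records$pIC50_obs)
    out$improvement_vs_best <- pred - baseline
    lev <- leverages(modeling_records, candidates, terms = model$terms)
    q <- lev$compounds[lev$compounds$set == "query", ]
    out$in_domain <- q$in_domain[match(out$compound_id, q$compound_id)]
  } else {
    out$improvement_vs_best <- NA_real_
    out$in_domain <- NA
  }
  class(out) <- c("candidate_predictions", class(out))
  out
}

#' Drug-likeness rule screening
#'
#' Applies the four classical oral drug-likeness filters to candidate
#' physicochemical property rows:
#'
#' * **Lipinski** (rule of five): violations counted over MW > 500 Da,
#'   LogP > 5, H-bond acceptors > 10, H-bond donors > 5; pass when at most
#'   one violation (the standard allowance).
#' * **Veber**: rotatable bonds <= 10 and TPSA <= 140 A^2.
#' * **Egan**: LogP and TPSA inside the passive-absorption ellipse; the
#'   default bounds (`LogP <= 6.26`, `TPSA <= 148.12 A^2`) are the
#'   99%-confidence ellipse. The tighter 95% bounds (5.88 / 131.6) can be
#'   supplied instead.
#' * **Muegge**: evaluated over the available properties
#'   (200 <= MW <= 600, -2 <= LogP <= 5, TPSA <= 150, rotatable <= 15,
#'   HBA <= 10, HBD <= 5); the ring- and atom-count conditions of the full
#'   published rule need structural information not carried here.
#'
#' Veber, Egan and Muegge pass only with zero violations. All predicates
#' are monotone: worsening a property can only add violations.
#'
#' @param properties Data frame (or single row) with columns `TPSA`,
#'   `n_rotatable`, `MW`, `LogP`, `n_HBA`, `n_HBD` and optionally
#'   `compound_id`.
#' @param egan_logp_max,egan_tpsa_max Egan ellipse bounds; defaults are the
#'   99%-confidence values.
#' @return A data frame of class `druglikeness_verdict` with one row per
#'   candidate: `lipinski_violations` (0-4), logical `lipinski`, `veber`,
#'   `egan`, `muegge` and `overall` (all four pass).
#' @examples
#' apply_druglikeness_rules(data.frame(TPSA = 115.55, n_rotatable = 6,
#'   MW = 473.55, LogP = 3.98, n_HBA = 9, n_HBD = 2))
#' @export
apply_druglikeness_rules <- function(properties,
                                     egan_logp_max = 6.26,
                                     egan_tpsa_max = 148.12) {
  req <- c("TPSA", "n_rotatable", "MW", "LogP", "n_HBA", "n_HBD")
  missing <- setdiff(req, names(properties))
  if (length(missing)) {
    stop("property row lacks: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  pr <- as.data.frame(properties)
  if (any(!is.finite(as.matrix(pr[, req])))) {
    stop("non-finite property values", call. = FALSE)
  }

  lip_viol <- (pr$MW > 500) + (pr$LogP > 5) + (pr$n_HBA > 10) + (pr$n_HBD > 5)
  out <- data.frame(
    compound_id = if ("compound_id" %in% names(pr)) as.character(pr$compound_id)
                  else as.character(seq_len(nrow(pr))),
    lipinski_violations = as.integer(lip_viol),
    lipinski = lip_viol <= 1L,
    veber = pr$n_rotatable <= 10 & pr$TPSA <= 140,
    egan = pr$LogP <= egan_logp_max & pr$TPSA <= egan_tpsa_max,
    muegge = pr$MW >= 200 & pr$MW <= 600 &
             pr$LogP >= -2 & pr$LogP <= 5 &
             pr$TPSA <= 150 & pr$n_rotatable <= 15 &
             pr$n_HBA <= 10 & pr$n_HBD <= 5,
    stringsAsFactors = FALSE
  )
  out$overall <- out$lipinski & out$veber & out$egan & out$muegge
  class(out) <- c("druglikeness_verdict", class(out))
  out
}
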