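# CNS-oriented ADMET screen. The probabilities themselves come from an
# external predictor and are consumed as a table; this module only applies
# the selection rules.

#' Read an ADMET probability table
#'
#' CSV with columns `compound_id`, `bbb` (blood-brain-barrier penetration
#' probability), `pgp_sub` and `pgp_inh` (P-glycoprotein substrate /
#' inhibitor probabilities), all in \[0,1\].
#'
#' @param path CSV path.
#' @return validated `data.frame`.
#' @export
read_admet_table <- function(path) {
  need <- c("compound_id", "bbb", "pgp_sub", "pgp_inh")
  header <- names(data.table::fread(path, nrows = 0L))
  if (!all(need %in% header)) {
    stop("ADMET table must have columns: ", paste(need, collapse = ", "))
  }
  dt <- data.table::fread(path, data.table = FALSE,
                          colClasses = list(character = "compound_id"))
  probs <- as.matrix(dt[c("bbb", "pgp_sub", "pgp_inh")])
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("ADMET probabilities must lie in [0,1]")
  }
  dt[need]
}

#' Screening policy for one target
#'
#' @param delta_g_max free-energy cutoff in kcal/mol (-9.2 for the strict
#'   criterion, -8.5 for the relaxed one).
#' @param bbb_min minimum BBB penetration probability (default 0.70).
#' @param pgp_max maximum P-gp substrate/inhibitor probability
#'   (default 0.50).
#' @return a `screen_policy` list.
#' @export
screen_policy <- function(delta_g_max, bbb_min = 0.70, pgp_max = 0.50) {
  stopifnot(bbb_min > 0, bbb_min < 1, pgp_max > 0, pgp_max < 1)
  structure(list(delta_g_max = delta_g_max, bbb_min = bbb_min,
                 pgp_max = pgp_max), class = "screen_policy")
}

#' Apply the CNS screen to predicted binders
#'
#' A compound passes iff its SMILES is a single connected fragment, its
#' predicted free energy is strictly below the policy cutoff, its BBB
#' probability is strictly above `bbb_min`, and both P-gp probabilities
#' are strictly below `pgp_max`. All comparisons are strict, consistent
#' with the extremes seen in published candidate tables (e.g. BBB 0.71
#' passing a 0.70 bar). Compounds without an ADMET record are excluded and
#' reported via the `unscreenable` attribute.
#'
#' @param compounds predictions from [predict_consensus()] (needs
#'   `compound_id`, `canonical_smiles`, `delta_g_pred`).
#' @param admet ADMET table from [read_admet_table()].
#' @param policy a [screen_policy()].
#' @return passing subset joined with its ADMET columns, sorted by
#'   `delta_g_pred` ascending; attribute `unscreenable` lists ids with no
#'   ADMET record.
#' @export
apply_cns_screen <- function(compounds, admet, policy) {
  stopifnot(inherits(policy, "screen_policy"))
  m <- match(compounds$compound_id, admet$compound_id)
  unscreenable <- compounds$compound_id[is.na(m) & !compounds$failed]
  if (length(unscreenable)) {
    message("apply_cns_screen: ", length(unscreenable),
            " compound(s) lack an ADMET record and are excluded")
  }
  dat <- cbind(compounds, admet[m, c("bbb", "pgp_sub", "pgp_inh")])
  ok_smiles <- !compounds$failed & !is.na(compounds$canonical_smiles)
  single <- rep(FALSE, nrow(dat))
  single[ok_smiles] <- !is_multifragment(dat$canonical_smiles[ok_smiles])
  keep <- single & !is.na(m) & !is.na(dat$delta_g_pred) &
    dat$delta_g_pred < policy$delta_g_max &
    dat$bbb > policy$bbb_min &
    dat$pgp_sub < policy$pgp_max &
    dat$pgp_inh < policy$pgp_max
  out <- dat[keep, , drop = FALSE]
  out <- out[order(out$delta_g_pred, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unscreenable") <- unscreenable
  out
}
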