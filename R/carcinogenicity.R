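#' Survival-adjusted bioassay record
#'
#' Holds the poly-3 survival-adjusted effective animal counts and tumor
#' proportions for one chemical's treated and control arms of a two-year
#' bioassay. Counts are real-valued: animals dying tumor-free before
#' terminal sacrifice contribute fractional weight.
#'
#' @param chemical_id character token.
#' @param n_treat,n_cont positive survival-adjusted animal counts.
#' @param p_treat,p_cont tumor proportions in `[0, 1]`.
#' @return object of class `bioassay_record`.
#' @export
bioassay_record <- function(chemical_id, n_treat, p_treat, n_cont, p_cont) {
  bad <- character()
  if (!is.numeric(n_treat) || n_treat <= 0) bad <- c(bad, "n_treat")
  if (!is.numeric(n_cont) || n_cont <= 0) bad <- c(bad, "n_cont")
  if (!is.numeric(p_treat) || p_treat < 0 || p_treat > 1) bad <- c(bad, "p_treat")
  if (!is.numeric(p_cont) || p_cont < 0 || p_cont > 1) bad <- c(bad, "p_cont")
  if (length(bad) > 0L) {
    stop("invalid bioassay record for '", chemical_id, "': ",
         paste(bad, collapse = ", "))
  }
  structure(list(chemical_id = as.character(chemical_id),
                 n_treat = n_treat, p_treat = p_treat,
                 n_cont = n_cont, p_cont = p_cont),
            class = "bioassay_record")
}

#' Poly-3 tumor-incidence z statistic
#'
#' Pooled two-proportion statistic on the survival-adjusted counts:
#' `phat = (n_t p_t + n_c p_c)/(n_t + n_c)` and
#' `z = (p_t - p_c) / sqrt(phat (1 - phat) (1/n_t + 1/n_c))`.
#' When the pooled proportion is degenerate (0 or 1) the statistic is 0.
#'
#' @param rec a [bioassay_record()].
#' @return scalar z.
#' @export
poly3_z <- function(rec) {
  stopifnot(inherits(rec, "bioassay_record"))
  phat <- (rec$n_treat * rec$p_treat + rec$n_cont * rec$p_cont) /
    (rec$n_treat + rec$n_cont)
  if (phat <= 0 || phat >= 1) return(0)
  (rec$p_treat - rec$p_cont) /
    sqrt(phat * (1 - phat) * (1 / rec$n_treat + 1 / rec$n_cont))
}

#' Cap extreme poly-3 statistics
#'
#' Upper outliers are truncated at the standard-normal critical value for
#' significance `alpha` (default `2e-5`), i.e. `min(z, qnorm(1 - alpha))`.
#' The lower tail is not capped: only extreme tumor increases are outliers
#' for the regression target.
#'
#' @param z numeric vector.
#' @param alpha upper-tail significance of the cap (default `2e-5`).
#' @return capped values.
#' @export
cap_z <- function(z, alpha = 2e-5) {
  pmin(z, stats::qnorm(1 - alpha))
}

#' Carcinogenicity call for a bioassay record
#'
#' One-sided upper-tail test for a tumor increase: `p = 1 - pnorm(z)`;
#' the chemical is called positive when `p <= 0.01` (equivalently
#' `z >= qnorm(0.99)`). Equivocal bioassay outcomes (one-sided p around
#' 0.075-0.084) map to negative under this rule.
#'
#' @param rec a [bioassay_record()].
#' @param p_threshold call threshold on the one-sided p (default 0.01).
#' @param cap_alpha passed to [cap_z()].
#' @return one-row data frame: `chemical_id`, `z_raw`, `z_capped`,
#'   `p_one_sided`, `call` (`"positive"`/`"negative"`).
#' @export
binary_call <- function(rec, p_threshold = 0.01, cap_alpha = 2e-5) {
  z <- poly3_z(rec)
  p <- stats::pnorm(z, lower.tail = FALSE)
  data.frame(chemical_id = rec$chemical_id,
             z_raw = z,
             z_capped = cap_z(z, alpha = cap_alpha),
             p_one_sided = p,
             call = if (p <= p_threshold) "positive" else "negative",
             stringsAsFactors = FALSE)
}

#' Poly-3 survival-adjusted counts from per-animal outcomes
#'
#' Each tumor-free animal dying at study-time fraction `t < 1` contributes
#' weight `t^3`; tumor-bearing animals and terminal survivors contribute 1.
#' The adjusted count is the sum of weights and the adjusted proportion is
#' the tumor count divided by it.
#'
#' @param death_time numeric vector in `(0, 1]`, death time as a fraction of
#'   the study duration (1 = terminal sacrifice).
#' @param tumor logical vector, tumor present at death.
#' @return list with `n_adj` and `p_adj`.
#' @export
poly3_adjusted_counts <- function(death_time, tumor) {
  if (length(death_time) == 0L) stop("no animals supplied")
  stopifnot(length(death_time) == length(tumor),
            all(death_time > 0), all(death_time <= 1))
  tumor <- as.logical(tumor)
  w <- ifelse(tumor, 1, death_time^3)
  n_adj <- sum(w)
  list(n_adj = n_adj, p_adj = sum(tumor) / n_adj)
}
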