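#' Structural cluster assignment for raspberry-ketone analogs
#'
#' The lure series splits into two structural groups: cluster 1 holds
#' compounds retaining both the phenolic ester group and the intact
#' 2-butanone side chain (cuelure and its ester homologs); cluster 2
#' holds compounds with either functionality modified (ethers, the free
#' phenol, or side-chain-modified esters). The label is determined
#' solely by the two structural flags.
#'
#' @param has_phenolic_ester,has_butanone_chain logical flags (vectorised).
#' @return integer vector of cluster labels (1 or 2).
#' @examples
#' assign_cluster(TRUE, TRUE)    # cuelure-like  -> 1
#' assign_cluster(FALSE, TRUE)   # methyl ether  -> 2
#' assign_cluster(TRUE, FALSE)   # modified side chain -> 2
#' @export
assign_cluster <- function(has_phenolic_ester, has_butanone_chain) {
  if (any(is.na(has_phenolic_ester)) || any(is.na(has_butanone_chain)))
    lv_stop("structural flags must be set (non-NA)", "lurevp_parameter_error")
  ifelse(has_phenolic_ester & has_butanone_chain, 1L, 2L)
}

#' ANCOVA of maximum response on structural cluster and vapour pressure
#'
#' Fits the compound-level linear model
#' `p_max ~ cluster + f(vp) + cluster:f(vp)` and reports sequential
#' (type I) sums of squares and F tests in that order, with residual
#' degrees of freedom `n - 4`. The covariate enters as `log10(vp)` by
#' default — the lure series spans three decades of vapour pressure — or
#' untransformed with `covariate_scale = "linear"`.
#'
#' Input must be compound-level (one row per compound, typically the
#' fitted `p_max` per lure); replicate-level data are rejected rather
#' than silently aggregated.
#'
#' @param pmax maximum response probabilities, one per compound.
#' @param vp vapour pressures in kPa, one per compound.
#' @param clusters cluster labels (see [assign_cluster()]); each cluster
#'   needs at least 2 members.
#' @param covariate_scale `"log10"` (default) or `"linear"`.
#' @param compound optional compound identifiers; duplicates trigger the
#'   replicate-level rejection.
#' @return A data frame of class `"ancova_table"` with columns `term`
#'   (`cluster`, `covariate`, `interaction`, `residual`), `df`, `SS`,
#'   `F`, `p`; the fitted `lm` is attached as attribute `"model"`.
#' @examples
#' reg <- lure_registry()
#' fits <- lure_response_reference()
#' d <- merge(fits, reg, by = "abbrev")
#' d <- merge(d, lure_vp_reference(), by = "abbrev")
#' ancova_pmax_vp(d$p_max, d$P_kPa, d$cluster)
#' @export
ancova_pmax_vp <- function(pmax, vp, clusters,
                           covariate_scale = c("log10", "linear"),
                           compound = NULL) {
  covariate_scale <- match.arg(covariate_scale)
  n <- length(pmax)
  if (length(vp) != n || length(clusters) != n)
    lv_stop("pmax, vp and clusters must have equal length",
            "lurevp_parameter_error")
  if (!is.null(compound) && anyDuplicated(compound))
    lv_stop(paste("replicate-level input detected (duplicated compounds);",
                  "supply one row per compound (e.g. fitted p_max means)"),
            "lurevp_parameter_error")
  if (n < 5L)
    lv_stop("need at least 5 compounds", "lurevp_insufficient_data")
  f <- factor(clusters)
  if (nlevels(f) != 2L || any(table(f) < 2L))
    lv_stop("need exactly 2 clusters with at least 2 compounds each",
            "lurevp_insufficient_data")
  if (any(vp <= 0))
    lv_stop("vapour pressures must be positive", "lurevp_domain_error")
  x <- if (covariate_scale == "log10") log10(vp) else vp

  model <- stats::lm(pmax ~ f + x + f:x)
  a <- stats::anova(model)
  out <- data.frame(
    term = c("cluster", "covariate", "interaction", "residual"),
    df = a$Df,
    SS = a$`Sum Sq`,
    F = c(a$`F value`[1:3], NA_real_),
    p = c(a$`Pr(>F)`[1:3], NA_real_))
  attr(out, "model") <- model
  attr(out, "covariate_scale") <- covariate_scale
  class(out) <- c("ancova_table", "data.frame")
  out
}

#' @export
print.ancova_table <- function(x, ...) {
  cat("ANCOVA of p_max on cluster +", attr(x, "covariate_scale"),
      "(vapour pressure), sequential SS\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
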