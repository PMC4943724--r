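#' Residual weight for a deregressed EBV record
#'
#' Computes w = lambda^-1 (d + c) with lambda = (1 - h2)/h2 and
#' d = (1 - r2)/r2, where r2 is the record's reliability (squared accuracy)
#' and h2 the trait heritability before deregression. The constant c
#' balances the contrast between high- and low-reliability records; with
#' c = 0 the weights are proportional to the classical deregression
#' weights d.
#'
#' @param r2 reliability in (0, 1]; vectorised.
#' @param h2 heritability in (0, 1).
#' @param c blending constant >= 0 (default 0.5).
#' @return numeric vector of weights.
#' @export
residualWeight <- function(r2, h2, c = 0.5) {
  if (any(r2 <= 0) || any(r2 > 1))
    stop("reliability r2 must be in (0, 1]")
  if (length(h2) != 1 || h2 <= 0 || h2 >= 1)
    stop("heritability h2 must be a scalar in (0, 1)")
  if (any(c < 0)) stop("c must be >= 0")
  lambda <- (1 - h2) / h2
  d <- (1 - r2) / r2
  (d + c) / lambda
}

#' Apply the minimum-accuracy filter to a trait
#'
#' Retains records whose accuracy meets \code{minAccuracy} (inclusive).
#' By default the threshold applies to the accuracy r = sqrt(reliability);
#' set \code{on = "reliability"} to apply it to r2 directly.
#'
#' @param trait a \code{\linkS4class{TraitData}} object.
#' @param minAccuracy threshold (default 0.50).
#' @param on \code{"accuracy"} (default) or \code{"reliability"}.
#' @return filtered \code{\linkS4class{TraitData}}.
#' @export
accuracyFilter <- function(trait, minAccuracy = 0.50,
                           on = c("accuracy", "reliability")) {
  on <- match.arg(on)
  rec <- records(trait)
  val <- if (on == "accuracy") sqrt(rec$reliability) else rec$reliability
  keep <- val >= minAccuracy
  if (!any(keep))
    stop("accuracy filter removed all records for trait ", traitId(trait))
  out <- trait
  out@records <- rec[keep, , drop = FALSE]
  rownames(out@records) <- NULL
  validObject(out)
  out
}
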