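#' Accessors for PairRegistry and MetricsSummary
#'
#' `totalReads()` is the denominator `t` behind every
#' "percentage of total reads" figure; `completePairs()` counts clones
#' with both end reads present; `pctPositioned()`,
#' `pctTailToTailOfTotal()`, `pctTailToTailOfPositioned()` and
#' `pctClonesTailToTail()` return the corresponding percentages in
#' [0, 100]. Percentages with a zero denominator are 0 by convention
#' (an evaluation in which nothing was positioned).
#'
#' @param x a [PairRegistry-class] or [MetricsSummary-class] object.
#' @return a single integer count or numeric percentage.
#' @examples
#' reg <- registryFromNames(c("C1.F", "C1.R", "C2.F"))
#' totalReads(reg)     # 3
#' completePairs(reg)  # 1
#' @name registry-accessors
NULL

#' @rdname registry-accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname registry-accessors
#' @export
setGeneric("totalClones", function(x) standardGeneric("totalClones"))

#' @rdname registry-accessors
#' @export
setGeneric("completePairs", function(x) standardGeneric("completePairs"))

#' @rdname registry-accessors
#' @export
setGeneric("readIds", function(x) standardGeneric("readIds"))

#' @rdname registry-accessors
#' @export
setGeneric("cloneIds", function(x) standardGeneric("cloneIds"))

#' @rdname registry-accessors
#' @export
setGeneric("pctPositioned", function(x) standardGeneric("pctPositioned"))

#' @rdname registry-accessors
#' @export
setGeneric("pctTailToTailOfTotal",
    function(x) standardGeneric("pctTailToTailOfTotal"))

#' @rdname registry-accessors
#' @export
setGeneric("pctTailToTailOfPositioned",
    function(x) standardGeneric("pctTailToTailOfPositioned"))

#' @rdname registry-accessors
#' @export
setGeneric("pctClonesTailToTail",
    function(x) standardGeneric("pctClonesTailToTail"))
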