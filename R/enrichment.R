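#' Build a pathway annotation map
#'
#' @param mapping data.frame (or two-column TSV path) with columns
#'   `metabolite_id` and `pathway_id`; one row per membership.
#' @return An object of class `annotation_map`: a named list of pathway
#'   member sets and the `universe` of annotatable metabolites (the union
#'   of all members). Empty pathways are impossible by construction.
#' @export
annotation_map <- function(mapping) {
  if (is.character(mapping) && length(mapping) == 1L) mapping <- read_tsv(mapping)
  mapping <- as.data.frame(mapping)
  if (ncol(mapping) < 2L) stop_gbl("annotation mapping needs two columns")
  names(mapping)[1:2] <- c("metabolite_id", "pathway_id")
  mapping <- unique(mapping[, 1:2])
  pathways <- split(mapping$metabolite_id, mapping$pathway_id)
  structure(list(pathways = pathways,
                 universe = sort(unique(mapping$metabolite_id))),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d pathways over a universe of %d metabolites\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Hypergeometric over-representation of a metabolite set
#'
#' For each pathway, tests whether the selected metabolites (e.g. the
#' PLSR-positive set) overlap the pathway more than expected when drawing
#' `n` metabolites at random from the universe of `N` annotatable
#' metabolites: upper-tail probability `P(X >= k)` with pathway size `K`
#' and overlap `k`, followed by Benjamini-Hochberg FDR across pathways.
#' Selected metabolites outside the universe are dropped (the selected-set
#' size `n` is the in-universe count).
#'
#' @param selected character vector of selected metabolite identifiers.
#' @param annotations an [annotation_map()].
#' @param universe optional character vector overriding the background
#'   (e.g. all metabolites that survived QC); intersected with the
#'   annotation universe.
#' @return data.frame sorted by p: `pathway_id`, `k`, `K`, `n`, `N`,
#'   `p_hyper`, `q_fdr`, `neg_log10_p`.
#' @export
enrich <- function(selected, annotations, universe = NULL) {
  stopifnot(inherits(annotations, "annotation_map"))
  uni <- annotations$universe
  if (!is.null(universe)) uni <- intersect(uni, universe)
  sel <- intersect(unique(selected), uni)
  if (!length(sel)) {
    unmapped <- setdiff(unique(selected), uni)
    stop_gbl("no selected metabolite maps to the annotation universe; unmapped: ",
             paste(utils::head(unmapped, 10), collapse = ", "))
  }
  nn <- length(sel); big_n <- length(uni)
  rows <- lapply(names(annotations$pathways), function(pw) {
    members <- intersect(annotations$pathways[[pw]], uni)
    if (!length(members)) return(NULL)
    kk <- length(intersect(sel, members)); big_k <- length(members)
    # P(X >= k) for X ~ Hypergeometric(N, K, n)
    p <- if (kk == 0) 1 else stats::phyper(kk - 1, big_k, big_n - big_k, nn,
                                           lower.tail = FALSE)
    data.frame(pathway_id = pw, k = kk, K = big_k, n = nn, N = big_n,
               p_hyper = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_fdr <- fdr_adjust(out$p_hyper)
  out$neg_log10_p <- -log10(out$p_hyper)
  out <- out[order(out$p_hyper, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
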