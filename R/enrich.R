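#' Hypergeometric pathway enrichment of coexpression modules
#'
#' For each module and pathway set, the upper-tail hypergeometric
#' probability of drawing at least the observed overlap: with background
#' size `N`, pathway size `K` (in background), module size `n` (in
#' background) and overlap `k`, `p = P(X >= k)` for
#' `X ~ Hypergeom(N, K, n)`. q-values are BH-adjusted across pathways
#' within each module; a row is significant when both `p` and `q` are
#' below `alpha`.
#'
#' @param modules named list of module gene sets (or a gene -> module
#'   assignment vector, `"grey"` excluded).
#' @param pathwaySets named list of pathway gene sets.
#' @param background character vector of background genes (the
#'   coexpression input universe by default conditioning of the
#'   selection procedure).
#' @param alpha significance level for both p and q (default 0.05).
#' @return data.frame: `module`, `pathway`, `overlap`, `module_size`,
#'   `pathway_size`, `background`, `p`, `q`, `significant`.
#' @export
hypergeomEnrich <- function(modules, pathwaySets, background, alpha = 0.05) {
    if (!length(background)) stop("empty background")
    if (is.character(modules) && !is.list(modules)) {
        asg <- modules[modules != "grey"]
        modules <- split(names(asg), asg)
    }
    if (!length(modules))
        return(data.frame(module = character(), pathway = character(),
                          overlap = integer(), module_size = integer(),
                          pathway_size = integer(), background = integer(),
                          p = numeric(), q = numeric(),
                          significant = logical()))
    N <- length(unique(background))
    out <- do.call(rbind, lapply(names(modules), function(m) {
        mg <- intersect(modules[[m]], background)
        n <- length(mg)
        rows <- do.call(rbind, lapply(names(pathwaySets), function(p) {
            pg <- intersect(pathwaySets[[p]], background)
            K <- length(pg)
            k <- length(intersect(mg, pg))
            pv <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
            data.frame(module = m, pathway = p, overlap = k,
                       module_size = n, pathway_size = K, background = N,
                       p = pv, stringsAsFactors = FALSE)
        }))
        rows$q <- p.adjust(rows$p, method = "BH")
        rows
    }))
    out$significant <- out$p < alpha & out$q < alpha
    out
}

#' Select the analysis module by autophagy content
#'
#' The module with the largest number of autophagy genes among its
#' members is chosen (ties broken in favour of the larger module), and
#' three-way overlap counts with the autophagy list and a reference
#' disease pathway gene set are reported for a Venn-style summary.
#'
#' @param assignment gene -> module labels (`"grey"` ignored).
#' @param autophagyGenes autophagy gene list.
#' @param adPathwayGenes optional reference disease-pathway gene set.
#' @return list: `module`, `autophagy_counts` (per module), `venn`
#'   (`module_autophagy`, `module_ad`, `module_both`).
#' @export
selectModule <- function(assignment, autophagyGenes,
                         adPathwayGenes = character(0)) {
    asg <- assignment[assignment != "grey"]
    if (!length(asg)) stop("no assigned modules")
    mods <- split(names(asg), asg)
    cnt <- vapply(mods, function(g)
        length(intersect(g, autophagyGenes)), integer(1))
    sz <- vapply(mods, length, integer(1))
    ord <- order(-cnt, -sz, names(mods))
    chosen <- names(mods)[ord[1]]
    g <- mods[[chosen]]
    list(module = chosen,
         autophagy_counts = cnt,
         venn = list(
             module_autophagy = length(intersect(g, autophagyGenes)),
             module_ad = length(intersect(g, adPathwayGenes)),
             module_both = length(intersect(intersect(g, autophagyGenes),
                                            adPathwayGenes))))
}
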