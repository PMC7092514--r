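#' Read an OBO-format ontology restricted to hierarchy edges
#'
#' Minimal stanza reader for `[Term]` blocks: `id`, `name`, `namespace`,
#' `is_a` and (optionally) `relationship: part_of` lines; obsolete terms are
#' dropped. Each namespace must contain exactly one root (a term with no
#' parents).
#'
#' @param path OBO file
#' @param includePartOf also treat `part_of` relationships as parent edges
#' @return an [OntologyDag]
#' @export
readObo <- function(path, includePartOf = FALSE) {
    lines <- readLines(path, warn = FALSE)
    idx <- which(lines == "[Term]")
    if (!length(idx)) stop("no [Term] stanza in ", path)
    bounds <- c(idx, length(lines) + 1L)
    ids <- character(0); nms <- character(0); ns <- character(0)
    parents <- list()
    for (k in seq_along(idx)) {
        block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
        val <- function(tag) sub(paste0("^", tag, ": *"), "",
                                 grep(paste0("^", tag, ": "), block, value = TRUE))
        if (length(val("is_obsolete")) && any(val("is_obsolete") == "true"))
            next
        id <- val("id")[1L]
        if (is.na(id) || !length(id)) next
        pa <- sub(" !.*$", "", val("is_a"))
        if (includePartOf) {
            rel <- val("relationship")
            po <- rel[startsWith(rel, "part_of ")]
            pa <- c(pa, sub(" !.*$", "", sub("^part_of ", "", po)))
        }
        ids <- c(ids, id)
        nms[id] <- if (length(val("name"))) val("name")[1L] else id
        ns[id] <- if (length(val("namespace"))) val("namespace")[1L] else "unknown"
        parents[[id]] <- unique(pa)
    }
    ## ignore dangling parent references (e.g. part_of targets outside file)
    parents <- lapply(parents, function(p) p[p %in% ids])
    rootless <- ids[lengths(parents[ids]) == 0L]
    roots <- stats::setNames(rootless, ns[rootless])
    if (anyDuplicated(names(roots)))
        stop("namespace with more than one root term")
    new("OntologyDag", terms = ids, parents = parents, namespace = ns,
        roots = roots, names = nms)
}

#' Read a two-column gene-to-term association table
#'
#' TSV with columns `gene_id` and `term` (header optional when exactly two
#' columns).
#'
#' @param path TSV path
#' @return data.frame with `gene_id`, `term`
#' @export
readGoAssociations <- function(path) {
    d <- utils::read.delim(path, colClasses = "character")
    if (!all(c("gene_id", "term") %in% colnames(d))) {
        if (ncol(d) == 2L) colnames(d) <- c("gene_id", "term")
        else stop("association table needs columns gene_id and term")
    }
    d[, c("gene_id", "term")]
}

## All strict ancestors of a term (BFS over parent edges).
.dagAncestors <- function(dag, term) {
    seen <- character(0)
    frontier <- dag@parents[[term]]
    while (length(frontier)) {
        seen <- union(seen, frontier)
        frontier <- setdiff(unique(unlist(dag@parents[frontier],
                                          use.names = FALSE)), seen)
    }
    seen
}

## Terms at exactly `depth` edges (shortest path) below a namespace root.
.dagLevel <- function(dag, namespaceRoot, depth = 1L) {
    level <- namespaceRoot
    seen <- namespaceRoot
    for (d in seq_len(depth)) {
        kids <- dag@terms[vapply(dag@terms, function(t)
            any(dag@parents[[t]] %in% level), logical(1))]
        level <- setdiff(kids, seen)
        seen <- union(seen, level)
    }
    level
}

#' Abstract an ontology term to its parent terms
#'
#' Returns the depth-`depth` descendants of the term's namespace root that
#' are ancestors of (or equal to) the term: the top-level categories the term
#' rolls up to. A term already at that depth maps to itself; a term reachable
#' through several top-level parents returns all of them; the namespace root
#' itself abstracts to nothing.
#'
#' @param term a term id
#' @param dag an [OntologyDag]
#' @param depth depth below the namespace root defining "parent" (default 1)
#' @return character vector of parent term ids (possibly empty); unknown
#'   terms warn and return empty
#' @export
abstractTerm <- function(term, dag, depth = 1L) {
    if (!term %in% dag@terms) {
        warning("unknown ontology term '", term, "' skipped")
        return(character(0))
    }
    root <- dag@roots[[dag@namespace[[term]]]]
    level <- .dagLevel(dag, root, depth)
    intersect(level, c(term, .dagAncestors(dag, term)))
}

#' Roll up each gene's annotations to parent terms
#'
#' @param assoc data.frame with `gene_id`, `term`
#' @param dag an [OntologyDag]
#' @param depth see [abstractTerm()]
#' @return named list: gene id -> unique character vector of parent terms
#' @export
genesToParents <- function(assoc, dag, depth = 1L) {
    cache <- new.env(parent = emptyenv())
    lookup <- function(t) {
        if (!is.null(cache[[t]])) return(cache[[t]])
        cache[[t]] <- abstractTerm(t, dag, depth)
        cache[[t]]
    }
    lapply(split(assoc$term, assoc$gene_id), function(terms)
        unique(unlist(lapply(unique(terms), lookup), use.names = FALSE)))
}

#' Deviation of spliced-gene GO parent terms from genomic expectation
#'
#' For each parent term: observed = number of spliced genes annotated to it
#' after abstraction (a gene counts once per parent no matter how many leaf
#' terms roll up to it); expected = genome parent proportion x number of
#' spliced genes; each term is tested against its complement with a 1-df
#' chi-square. The reported `deviation` follows the figure convention
#' (observed - expected) / total events in the tissue. Parent terms covering
#' less than `minGenomeFrac` of the genome (default 2%) are excluded from
#' the report.
#'
#' @param splicedGenes character vector of gene ids (within the genome
#'   universe the expectation was built on)
#' @param assoc data.frame `gene_id`, `term`
#' @param dag an [OntologyDag]
#' @param expectation an [ExpectationModel] with GO parent proportions
#' @param tissueTotal total events in the tissue used as the normalizer
#'   (defaults to the number of spliced genes)
#' @param minGenomeFrac genome-abundance report filter (default 0.02)
#' @param depth see [abstractTerm()]
#' @return data.frame `parent`, `name`, `genome_proportion`, `observed`,
#'   `expected`, `deviation`, `statistic`, `df`, `p`
#' @export
goDeviationTest <- function(splicedGenes, assoc, dag, expectation,
                            tissueTotal = NULL, minGenomeFrac = 0.02,
                            depth = 1L) {
    props <- goParentProportions(expectation)
    empty <- data.frame(parent = character(0), name = character(0),
                        genome_proportion = numeric(0), observed = integer(0),
                        expected = numeric(0), deviation = numeric(0),
                        statistic = numeric(0), df = integer(0), p = numeric(0))
    if (!length(splicedGenes)) {
        warning("empty spliced gene set")
        return(empty)
    }
    if (!length(props)) {
        warning("expectation model has no GO parent proportions")
        return(empty)
    }
    if (is.null(tissueTotal)) tissueTotal <- length(splicedGenes)
    parentsByGene <- genesToParents(
        assoc[assoc$gene_id %in% splicedGenes, , drop = FALSE], dag, depth)
    nSpliced <- length(splicedGenes)
    rows <- lapply(names(props), function(term) {
        obs <- sum(vapply(parentsByGene, function(p) term %in% p, logical(1)))
        expd <- props[[term]] * nSpliced
        ht <- if (props[[term]] < 1)
            suppressWarnings(stats::chisq.test(
                c(obs, nSpliced - obs), p = c(props[[term]], 1 - props[[term]])))
        else list(statistic = 0, p.value = 1)
        data.frame(parent = term,
                   name = if (term %in% names(dag@names)) dag@names[[term]] else term,
                   genome_proportion = props[[term]], observed = obs,
                   expected = expd, deviation = (obs - expd) / tissueTotal,
                   statistic = unname(ht$statistic), df = 1L,
                   p = unname(ht$p.value))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[out$genome_proportion >= minGenomeFrac, , drop = FALSE]
}
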