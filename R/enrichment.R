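#' Read / write GMT gene-set libraries
#'
#' Standard GMT: one term per line, tab-separated as
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}.  Gene symbols are
#' upper-cased on read for consistent matching; duplicate term names are an
#' error, malformed lines report their line number.
#'
#' @param path GMT file.
#' @return list of class \code{"GmtLibrary"}: \code{terms} (named list of
#'   character vectors), \code{descriptions}, \code{source} (the path).
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
        warning("empty GMT file: ", path, call. = FALSE)
        return(structure(list(terms = list(),
                              descriptions = character(0), source = path),
                         class = "GmtLibrary"))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad))
        stop("malformed GMT line ", bad[1L], " in ", path,
             " (need name, description and >= 1 gene)")
    names <- vapply(parts, `[[`, character(1), 1L)
    if (anyDuplicated(names))
        stop("duplicate GMT term name(s): ",
             paste(unique(names[duplicated(names)]), collapse = ", "))
    terms <- lapply(parts, function(x) unique(toupper(x[-(1:2)])))
    names(terms) <- names
    structure(list(terms = terms,
                   descriptions = setNames(
                       vapply(parts, `[[`, character(1), 2L), names),
                   source = path),
              class = "GmtLibrary")
}

#' @rdname readGmt
#' @param lib a \code{GmtLibrary}.
#' @export
writeGmt <- function(lib, path) {
    stopifnot(inherits(lib, "GmtLibrary"))
    lines <- vapply(names(lib$terms), function(nm)
        paste(c(nm, lib$descriptions[[nm]], lib$terms[[nm]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each library term, tests whether the query list overlaps the term
#' more than expected by chance within the gene universe: upper-tail
#' hypergeometric \eqn{p = P(X \ge k)} for overlap k, term size K (after
#' intersection with the universe), query size n and universe size N, with
#' Benjamini-Hochberg correction across the terms of the library.
#'
#' @param query character vector of gene symbols (must lie in the
#'   universe).
#' @param lib a \code{\link{readGmt}} library.
#' @param universe character vector of testable genes (convention: all
#'   genes in the expression matrix, not all genes in the library).
#' @return data.frame sorted by p: columns \code{term}, \code{overlap},
#'   \code{termSize}, \code{querySize}, \code{universeSize}, \code{p},
#'   \code{q}, \code{genes} (comma-separated overlap).
#' @export
oraHypergeometric <- function(query, lib, universe) {
    stopifnot(inherits(lib, "GmtLibrary"))
    query <- unique(toupper(query))
    universe <- unique(toupper(universe))
    if (!length(query)) stop("empty query gene list")
    if (!length(universe)) stop("empty universe")
    if (!all(query %in% universe))
        stop("query genes outside the universe: ",
             paste(setdiff(query, universe)[1:5], collapse = ", "))
    N <- length(universe)
    n <- length(query)
    rows <- lapply(names(lib$terms), function(nm) {
        term <- intersect(lib$terms[[nm]], universe)
        K <- length(term)
        if (!K) return(NULL)
        hit <- intersect(query, term)
        k <- length(hit)
        p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(term = nm, overlap = k, termSize = K, querySize = n,
                   universeSize = N, p = p,
                   genes = paste(sort(hit), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(term = character(), overlap = integer(),
                          termSize = integer(), querySize = integer(),
                          universeSize = integer(), p = numeric(),
                          q = numeric(), genes = character(),
                          stringsAsFactors = FALSE))
    out$q <- bhAdjust(out$p)
    out <- out[order(out$p, out$term), c("term", "overlap", "termSize",
                                         "querySize", "universeSize",
                                         "p", "q", "genes")]
    rownames(out) <- NULL
    out
}

#' Cross-cancer transcription-factor target overlap
#'
#' For each transcription factor, intersects its per-cancer target-DEG sets
#' across all cancers (the "common targets"), then forms the union of the
#' per-TF common-target sets with each gene counted once.
#'
#' @param perCancerHits named list: cancer -> named list (TF -> character
#'   vector of target genes).
#' @param tfs transcription factors to evaluate; a TF absent from a cancer
#'   is treated as an empty set with a warning.
#' @return list of class \code{"TfTargetOverlap"}: \code{perTf} (named list
#'   of common-target vectors), \code{counts} (named integer), \code{union}
#'   (de-duplicated character vector), \code{unionCount}.
#' @export
commonTfTargets <- function(perCancerHits, tfs) {
    stopifnot(length(perCancerHits) >= 1L)
    perTf <- lapply(tfs, function(tf) {
        sets <- lapply(names(perCancerHits), function(cc) {
            s <- perCancerHits[[cc]][[tf]]
            if (is.null(s)) {
                warning("TF ", tf, " absent in cancer ", cc,
                        "; treated as empty", call. = FALSE)
                character(0)
            } else unique(toupper(s))
        })
        sort(Reduce(intersect, sets))
    })
    names(perTf) <- tfs
    un <- sort(unique(unlist(perTf)))
    structure(list(perTf = perTf,
                   counts = vapply(perTf, length, integer(1)),
                   union = un, unionCount = length(un)),
              class = "TfTargetOverlap")
}
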