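#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-separated. Duplicate members are removed with a warning; lines
#' with fewer than three fields or no members raise a parse error naming
#' the line.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (members), with the
#'   descriptions in `attr(, "description")`.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list()
    desc <- character()
    for (i in seq_along(lines)) {
        parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3L)
            stop(sprintf("malformed GMT line %d: expected name, description and >= 1 member",
                         i))
        members <- parts[-(1:2)]
        members <- members[nzchar(members)]
        if (!length(members))
            stop(sprintf("malformed GMT line %d: empty member list", i))
        if (anyDuplicated(members)) {
            warning(sprintf("duplicate members in set '%s' deduplicated",
                            parts[1L]))
            members <- unique(members)
        }
        sets[[parts[1L]]] <- members
        desc[parts[1L]] <- parts[2L]
    }
    attr(sets, "description") <- desc
    sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional named character vector of descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, description = NULL) {
    if (is.null(description))
        description <- attr(sets, "description")
    lines <- vapply(names(sets), function(nm) {
        d <- if (!is.null(description) && nm %in% names(description))
            description[[nm]] else nm
        paste(c(nm, d, sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Normalize a GO-style accession
#'
#' Strips thousands separators sometimes introduced by typesetting
#' (e.g. `"GO:0,000,278"`) and zero-pads the numeric part to seven
#' digits.
#'
#' @param id character vector of accessions.
#' @return normalized accessions.
#' @export
normalizeGoId <- function(id) {
    num <- gsub(",", "", sub("^GO:", "", id), fixed = TRUE)
    ifelse(grepl("^[0-9]+$", num),
           sprintf("GO:%07d", as.integer(num)), id)
}

#' Build gene sets from annotation records with evidence filtering
#'
#' Retains records whose evidence code is in the allowed set (default:
#' the direct experimental codes EXP, IDA, IPI, IMP, IGI, IEP), whose
#' taxon matches, and whose gene type is protein-coding, then aggregates
#' the surviving records into gene sets keyed by (normalized) accession.
#' A gene is retained in a set if *any* of its records qualifies.
#'
#' @param records data.frame with columns `gene`, `accession`,
#'   `evidence`, `taxon`, `type`.
#' @param evidence allowed evidence codes.
#' @param taxon required taxon label (default `"9606"`, human).
#' @param type required gene-type label (default `"protein_coding"`).
#' @return named list of character vectors (unique member genes, sorted).
#' @export
filterAnnotations <- function(records,
                              evidence = c("EXP", "IDA", "IPI", "IMP",
                                           "IGI", "IEP"),
                              taxon = "9606",
                              type = "protein_coding") {
    need <- c("gene", "accession", "evidence", "taxon", "type")
    miss <- setdiff(need, colnames(records))
    if (length(miss))
        stop("records missing column(s): ", paste(miss, collapse = ", "))
    keep <- records$evidence %in% evidence &
        records$taxon == taxon & records$type == type
    rec <- records[keep, , drop = FALSE]
    if (!nrow(rec)) return(setNames(list(), character()))
    acc <- normalizeGoId(rec$accession)
    out <- lapply(split(rec$gene, acc), function(g) sort(unique(g)))
    out[order(names(out))]
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the observed overlap between the query and the set
#' when `|query|` genes are drawn from the background universe without
#' replacement. Sets are intersected with the background first; p-values
#' are BH-adjusted across sets.
#'
#' @param query character vector of genes of interest (must be a subset
#'   of `background`).
#' @param background character vector, the gene universe (typically the
#'   post-filter transcriptome).
#' @param sets named list of character vectors.
#' @return data.frame with columns `set`, `overlap`, `querySize`,
#'   `setSize`, `backgroundSize`, `p`, `adjP`, ordered by `p`.
#' @examples
#' bg <- paste0("g", 1:20)
#' ora(bg[1:5], bg, list(hit = bg[1:5]))
#' @export
ora <- function(query, background, sets) {
    query <- unique(query)
    background <- unique(background)
    outside <- setdiff(query, background)
    if (length(outside))
        stop("query gene(s) outside background: ",
             paste(head(outside, 5L), collapse = ", "))
    rows <- lapply(names(sets), function(nm) {
        s <- intersect(unique(sets[[nm]]), background)
        ov <- length(intersect(query, s))
        p <- phyper(ov - 1L, length(s), length(background) - length(s),
                    length(query), lower.tail = FALSE)
        data.frame(set = nm, overlap = ov, querySize = length(query),
                   setSize = length(s), backgroundSize = length(background),
                   p = p, row.names = NULL)
    })
    res <- do.call(rbind, rows)
    res$adjP <- adjustBH(res$p)
    res[order(res$p, res$set), , drop = FALSE]
}

#' The nine endothelial-function categories
#'
#' Returns the shipped mapping from GO anchor terms to the nine key
#' endothelial-cell function categories (mitotic cell cycle,
#' angiogenesis, regulation of cell adhesion, inflammatory response,
#' epithelial-to-mesenchymal transition, programmed cell death,
#' hemostasis, regulation of vascular permeability, regulation of blood
#' pressure). Users can extend the map with additional term-to-category
#' rows.
#'
#' @return data.frame with columns `accession`, `term`, `category`.
#' @export
endothelialCategories <- function() {
    path <- system.file("extdata", "endothelial_function_categories.tsv",
                        package = "medivar", mustWork = TRUE)
    read.delim(path, stringsAsFactors = FALSE)
}

#' Roll significant terms up into function categories
#'
#' Counts significant terms (adjusted p < alpha) per category of the
#' supplied map. Terms without a category mapping are counted under
#' `"unmapped"`, never silently dropped; every category of the map
#' appears in the output even at count zero.
#'
#' @param results an ORA result data.frame (from [ora()]) or a character
#'   vector of already-significant term accessions.
#' @param map data.frame with columns `accession` and `category`
#'   (default: [endothelialCategories()]).
#' @param alpha significance level on adjusted p (default 0.05; ignored
#'   for a character-vector input).
#' @return named integer vector of per-category term counts (plus
#'   `unmapped`).
#' @export
categorizeTerms <- function(results, map = endothelialCategories(),
                            alpha = 0.05) {
    terms <- if (is.character(results)) results
             else results$set[results$adjP < alpha]
    terms <- normalizeGoId(terms)
    cats <- map$category[match(terms, normalizeGoId(map$accession))]
    cats[is.na(cats)] <- "unmapped"
    levels <- c(unique(map$category), "unmapped")
    counts <- table(factor(cats, levels = levels))
    out <- setNames(as.integer(counts), levels)
    out
}
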