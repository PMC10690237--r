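#' Gene sets and consensus curation
#'
#' Published senescence gene sets disagree heavily: pairwise Jaccard indices
#' are typically below 0.2 and most genes appear in a single list. The
#' functions here represent gene sets (optionally with per-gene
#' induce/inhibit direction), count how many lists report each gene, and
#' distill a consensus signature of genes reported by at least `min_sets`
#' lists.
#'
#' @name genesets
NULL

#' Construct a gene set
#'
#' @param name set name.
#' @param genes character vector of gene symbols; whitespace is trimmed and
#'   duplicates removed.
#' @param direction optional named character vector mapping a subset of
#'   `genes` to `"induce"`, `"inhibit"` or `"unknown"`.
#' @param uppercase if `TRUE`, symbols are uppercased (useful when mixing
#'   mouse and human conventions; orthology mapping itself is up to the
#'   caller via [map_symbols()]).
#' @return a `gene_set` object (list with `name`, `genes`, `direction`).
#' @export
gene_set <- function(name, genes, direction = NULL, uppercase = FALSE) {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (uppercase) genes <- toupper(genes)
  genes <- unique(genes)
  if (!is.null(direction)) {
    if (uppercase) names(direction) <- toupper(names(direction))
    bad <- setdiff(names(direction), genes)
    if (length(bad)) stopf("direction given for genes not in the set: %s",
                           paste(bad, collapse = ", "))
    ok <- direction %in% c("induce", "inhibit", "unknown")
    if (!all(ok)) stopf("direction values must be induce/inhibit/unknown")
  }
  structure(list(name = as.character(name), genes = genes,
                 direction = direction), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes", x$name, length(x$genes)))
  if (!is.null(x$direction))
    cat(sprintf(" (%d with direction)", length(x$direction)))
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Construct a collection of gene sets
#'
#' @param sets a list of [gene_set()] objects with unique names.
#' @return a `gene_set_collection` (list with `sets` and the `universe`,
#'   the exact union of all member genes).
#' @export
gene_set_collection <- function(sets) {
  if (!length(sets)) stopf("collection must contain at least one gene set")
  stopifnot(all(vapply(sets, inherits, logical(1), "gene_set")))
  nms <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stopf("gene set names must be unique")
  names(sets) <- nms
  structure(list(sets = sets,
                 universe = unique(unlist(lapply(sets, `[[`, "genes")))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, %d genes in universe\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Count, for every gene, how many sets report it
#'
#' @param collection a [gene_set_collection()].
#' @return a tibble with columns `gene` and `n_sets` (1..number of sets),
#'   one row per universe gene.
#' @export
membership_counts <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  tab <- table(unlist(lapply(collection$sets, `[[`, "genes")))
  tibble::tibble(gene = names(tab), n_sets = as.integer(tab))
}

# majority direction for one gene across source sets; ties -> unknown
.majority_direction <- function(dirs) {
  dirs <- dirs[dirs %in% c("induce", "inhibit")]
  if (!length(dirs)) return("unknown")
  ni <- sum(dirs == "induce"); nh <- sum(dirs == "inhibit")
  if (ni > nh) "induce" else if (nh > ni) "inhibit" else "unknown"
}

#' Curate a consensus gene set
#'
#' Retains the genes reported by at least `min_sets` member sets. When one
#' or more source sets annotate a retained gene with a direction, the
#' majority direction across sets is attached (ties become `"unknown"`).
#'
#' @param collection a [gene_set_collection()].
#' @param min_sets minimum number of reporting sets (default 5).
#' @param name name for the resulting set.
#' @return a [gene_set()]; possibly empty.
#' @export
curate_consensus <- function(collection, min_sets = 5L,
                             name = "consensus") {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (min_sets < 1L || min_sets > length(collection$sets))
    stopf("`min_sets` must lie in 1..%d", length(collection$sets))
  mc <- membership_counts(collection)
  keep <- mc$gene[mc$n_sets >= min_sets]
  dir <- NULL
  if (length(keep)) {
    dl <- lapply(keep, function(g) {
      d <- vapply(collection$sets, function(s) {
        if (!is.null(s$direction) && g %in% names(s$direction))
          s$direction[[g]] else NA_character_
      }, character(1))
      .majority_direction(d[!is.na(d)])
    })
    has <- vapply(keep, function(g)
      any(vapply(collection$sets, function(s)
        !is.null(s$direction) && g %in% names(s$direction), logical(1))),
      logical(1))
    if (any(has)) dir <- stats::setNames(unlist(dl), keep)[has]
  }
  gene_set(name, keep, direction = dir)
}

#' Filter SeneQuest-style literature records into a gene set
#'
#' A gene is retained if it was reported by at least `min_pubs`
#' publications, or by at least `alt_min_pubs` publications with at least
#' `min_agreement` agreement on whether it induces or inhibits senescence.
#' Genes retained only through the agreement clause carry the majority
#' direction.
#'
#' @param records data frame with columns `gene`, `n_publications`,
#'   `n_induce`, `n_inhibit` (see [read_senequest_tsv()]).
#' @param min_pubs publication-count clause threshold (default 15).
#' @param alt_min_pubs publication threshold for the agreement clause
#'   (default 4).
#' @param min_agreement minimum directional agreement fraction (default
#'   0.7, applied as `>=`).
#' @param name name for the resulting gene set.
#' @return a [gene_set()] with directions where the agreement clause fired.
#' @export
filter_senequest <- function(records, min_pubs = 15L, alt_min_pubs = 4L,
                             min_agreement = 0.7, name = "senequest") {
  req <- c("gene", "n_publications", "n_induce", "n_inhibit")
  if (!all(req %in% names(records)))
    stopf("records must have columns %s", paste(req, collapse = ", "))
  if (anyDuplicated(records$gene)) stopf("records must have unique genes")
  with(records, {
    if (any(n_induce + n_inhibit > n_publications))
      stopf("directional reports exceed publication counts")
  })
  ndir <- records$n_induce + records$n_inhibit
  agree <- ifelse(ndir > 0, pmax(records$n_induce, records$n_inhibit) / ndir, 0)
  clause1 <- records$n_publications >= min_pubs
  clause2 <- records$n_publications >= alt_min_pubs & ndir > 0 &
    agree >= min_agreement
  keep <- clause1 | clause2
  genes <- records$gene[keep]
  # direction attached where the agreement clause applies
  dsel <- keep & clause2
  dir <- NULL
  if (any(dsel)) {
    dd <- ifelse(records$n_induce[dsel] > records$n_inhibit[dsel], "induce",
                 ifelse(records$n_inhibit[dsel] > records$n_induce[dsel],
                        "inhibit", "unknown"))
    dir <- stats::setNames(dd, records$gene[dsel])
  }
  gene_set(name, genes, direction = dir)
}

#' Jaccard index between two gene sets
#'
#' @param a,b [gene_set()] objects (at least one non-empty).
#' @return `|a n b| / |a u b|`, in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  u <- union(a$genes, b$genes)
  if (!length(u)) stopf("Jaccard index undefined for two empty sets")
  length(intersect(a$genes, b$genes)) / length(u)
}

#' Pairwise Jaccard matrix for a collection
#'
#' @param collection a [gene_set_collection()].
#' @return symmetric matrix of Jaccard indices, unit diagonal.
#' @export
jaccard_matrix <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  k <- length(collection$sets)
  m <- diag(1, k)
  dimnames(m) <- list(names(collection$sets), names(collection$sets))
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k)
    m[i, j] <- m[j, i] <- jaccard_index(collection$sets[[i]],
                                        collection$sets[[j]])
  m
}

#' Remap gene symbols through a user-supplied table
#'
#' Two-column orthology/alias mapping (e.g. mouse to human symbols from
#' MGI). Unmapped genes are dropped.
#'
#' @param set a [gene_set()].
#' @param mapping data frame whose first column holds current symbols and
#'   second column replacement symbols.
#' @return a remapped [gene_set()].
#' @export
map_symbols <- function(set, mapping) {
  stopifnot(inherits(set, "gene_set"), ncol(mapping) >= 2)
  from <- trimws(as.character(mapping[[1]])); to <- trimws(as.character(mapping[[2]]))
  idx <- match(set$genes, from)
  new <- to[idx]
  keep <- !is.na(new)
  dir <- NULL
  if (!is.null(set$direction)) {
    dn <- new[match(names(set$direction), set$genes)]
    ok <- !is.na(dn)
    if (any(ok)) dir <- stats::setNames(unname(set$direction)[ok], dn[ok])
  }
  gene_set(set$name, new[keep], direction = dir)
}

# ---- IO -------------------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then one gene per field.
#'
#' @param path file path.
#' @param uppercase passed to [gene_set()].
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, uppercase = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: %s", substr(l, 1, 40))
    gene_set(f[1], f[-(1:2)], uppercase = uppercase)
  })
  gene_set_collection(sets)
}

#' Write gene sets to a GMT file
#'
#' @param collection a [gene_set_collection()] or single [gene_set()].
#' @param path output file path.
#' @export
write_gmt <- function(collection, path) {
  sets <- if (inherits(collection, "gene_set")) list(collection)
          else collection$sets
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column gene/direction TSV as a gene set
#'
#' First column gene symbol; optional second column direction
#' (induce/inhibit/unknown).
#'
#' @param path file path.
#' @param name set name (default: file base name).
#' @param uppercase passed to [gene_set()].
#' @return a [gene_set()].
#' @export
read_gene_tsv <- function(path, name = NULL, uppercase = FALSE) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  nm <- name %||% sub("\\.[^.]*$", "", basename(path))
  dir <- NULL
  if (ncol(df) >= 2 && any(nzchar(trimws(df[[2]]))))
    dir <- stats::setNames(trimws(df[[2]]), trimws(df[[1]]))
  gene_set(nm, df[[1]], direction = dir, uppercase = uppercase)
}

#' Read SeneQuest-style literature records
#'
#' Expects columns gene, n_publications, n_induce, n_inhibit (header
#' optional, detected from the first line).
#'
#' @param path TSV file path.
#' @return tibble of records suitable for [filter_senequest()].
#' @export
read_senequest_tsv <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("gene", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (!header) names(df) <- c("gene", "n_publications", "n_induce", "n_inhibit")[seq_len(ncol(df))]
  tibble::as_tibble(df)
}

#' The bundled default senescence scoring signature
#'
#' A 39-gene consensus-style senescence signature with induce/inhibit
#' directions, shipped as the package's default scoring gene set. It is a
#' constructed stand-in assembled from canonical senescence marker genes
#' (CDKN1A, CDKN2A, SASP cytokines and proteases, and proliferation genes
#' that senescence represses), not a published supplementary list; users
#' reproducing a published analysis should supply their own signature via
#' [read_gmt()] or [read_gene_tsv()].
#'
#' @return a [gene_set()] of 39 genes with directions.
#' @export
default_signature <- function() {
  gmt <- system.file("extdata", "consensus_senescence_synthetic.gmt",
                     package = "senoscore", mustWork = TRUE)
  dirf <- system.file("extdata", "consensus_senescence_synthetic_directions.tsv",
                      package = "senoscore", mustWork = TRUE)
  set <- read_gmt(gmt)$sets[[1]]
  dir <- utils::read.delim(dirf, header = TRUE, stringsAsFactors = FALSE)
  gene_set(set$name, set$genes,
           direction = stats::setNames(dir$direction, dir$gene))
}
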