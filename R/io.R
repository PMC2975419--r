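# Readers and writers for every external table the pipeline touches.
# Dialect: tab-separated, UTF-8, '#'-prefixed comment lines ignored, no
# quoting. All readers return plain in-memory structures; downstream modules
# never touch files.

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(trimws(lines, "left"), "#") & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

split_tsv <- function(lines, lineno, min_cols, what) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_cols)
  if (length(bad)) {
    stop("malformed ", what, " row at line ", lineno[bad[1L]],
         ": expected >= ", min_cols, " tab-separated columns, got ",
         nf[bad[1L]])
  }
  fields
}

#' Read a pair-list TSV
#'
#' Reads a two-or-three column tab-separated file of protein pairs
#' (`protein_a`, `protein_b`, optional numeric `score`). Pairs are
#' canonicalized (lexicographically smaller identifier first), self-pairs are
#' dropped with a message, and duplicate rows are merged keeping the maximum
#' score. Lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @param has_score If `TRUE` the third column is read as a numeric score.
#' @return data.frame with columns `protein_a`, `protein_b`, optional
#'   `score`, and the canonical `key`.
#' @export
read_pair_table <- function(path, has_score = FALSE) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    warning("empty pair table: ", path)
    out <- data.frame(protein_a = character(0), protein_b = character(0),
                      stringsAsFactors = FALSE)
    if (has_score) out$score <- numeric(0)
    out$key <- character(0)
    return(out)
  }
  fields <- split_tsv(tl$lines, tl$lineno, if (has_score) 3L else 2L,
                      "pair table")
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    i <- which(!nzchar(a) | !nzchar(b))[1L]
    stop("empty protein identifier at line ", tl$lineno[i])
  }
  df <- data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
  if (has_score) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    if (anyNA(sc)) {
      stop("non-numeric score at line ", tl$lineno[which(is.na(sc))[1L]])
    }
    df$score <- sc
  }
  canonicalize_pairs(df)
}

#' Write a pair table as TSV
#'
#' @param df data.frame with `protein_a`, `protein_b` and optionally `score`.
#' @param path Output path.
#' @export
write_pair_table <- function(df, path) {
  cols <- intersect(c("protein_a", "protein_b", "score"), names(df))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a Gene Ontology OBO file into a DAG
#'
#' Parses `[Term]` stanzas of an OBO 1.2 file, keeping `is_a` and (by
#' default) `relationship: part_of` edges as ancestry. Obsolete terms are
#' excluded. The result is validated: every parent reference must resolve and
#' the graph must be acyclic.
#'
#' @param path Path to the OBO file.
#' @param part_of Treat `part_of` relationships as ancestry (default `TRUE`).
#' @return An `ontology_dag`: list with `terms` (character), `parents` (named
#'   list term -> character vector of parents), `namespace` (named character,
#'   values `BP`/`CC`/`MF` or `NA`), `name` (named character).
#' @export
read_obo <- function(path, part_of = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  other_starts <- grep("^\\[", lines)
  terms <- character(0)
  parents <- list()
  namespace <- character(0)
  name <- character(0)
  for (s in stanza_starts) {
    nxt <- other_starts[other_starts > s]
    e <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):e]
    get_vals <- function(tag) {
      hits <- block[startsWith(block, paste0(tag, ":"))]
      trimws(sub(paste0("^", tag, ":"), "", hits))
    }
    id <- get_vals("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    par <- sub("\\s*!.*$", "", get_vals("is_a"))
    if (part_of) {
      rel <- get_vals("relationship")
      po <- rel[startsWith(rel, "part_of")]
      par <- c(par, trimws(sub("\\s*!.*$", "", sub("^part_of\\s+", "", po))))
    }
    ns <- get_vals("namespace")
    terms <- c(terms, id)
    parents[[id]] <- unique(par[nzchar(par)])
    namespace[id] <- if (length(ns)) obo_namespace_code(ns[1L]) else NA_character_
    nm <- get_vals("name")
    name[id] <- if (length(nm)) nm[1L] else NA_character_
  }
  if (anyDuplicated(terms)) stop("duplicate term id in OBO file")
  dag <- new_ontology_dag(terms, parents, namespace, name)
  dag
}

obo_namespace_code <- function(x) {
  switch(x,
         biological_process = "BP",
         cellular_component = "CC",
         molecular_function = "MF",
         NA_character_)
}

#' Construct and validate an ontology DAG
#'
#' @param terms Character vector of term ids.
#' @param parents Named list mapping each term to its parent term ids.
#' @param namespace Optional named character (`BP`/`CC`/`MF`) per term.
#' @param name Optional named character of human-readable names.
#' @return An `ontology_dag` object.
#' @export
new_ontology_dag <- function(terms, parents, namespace = NULL, name = NULL) {
  terms <- as.character(terms)
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else p)
  all_par <- unique(unlist(parents, use.names = FALSE))
  dangling <- setdiff(all_par, terms)
  if (length(dangling)) {
    stop("dangling parent reference(s): ", paste(dangling, collapse = ", "))
  }
  dag <- structure(list(terms = terms, parents = parents,
                        namespace = namespace, name = name),
                   class = "ontology_dag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    stop("ontology graph is cyclic: ", paste(cyc, collapse = " -> "))
  }
  dag
}

# returns one cycle as a character vector, or NULL if acyclic (Kahn's algorithm)
find_cycle <- function(dag) {
  indeg <- vapply(dag$parents, length, 0L)
  # reverse edges: parent -> children
  children <- split(
    rep(names(dag$parents), lengths(dag$parents)),
    unlist(dag$parents, use.names = FALSE)
  )
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(dag$terms)) return(NULL)
  # walk parent links from a remaining node until a repeat
  rem <- names(indeg)[indeg > 0L]
  path <- rem[1L]
  repeat {
    nxt <- intersect(dag$parents[[path[length(path)]]], rem)[1L]
    if (nxt %in% path) {
      return(c(path[which(path == nxt)[1L]:length(path)], nxt))
    }
    path <- c(path, nxt)
  }
}

#' All ancestors of ontology terms
#'
#' Transitive closure over `is_a`/`part_of` parents. Optionally includes the
#' query terms themselves.
#'
#' @param dag An `ontology_dag`.
#' @param terms Character vector of term ids.
#' @param include_self Include the query terms in the result (default FALSE).
#' @return Character vector of ancestor term ids (union over `terms`).
#' @export
ontology_ancestors <- function(dag, terms, include_self = FALSE) {
  closure <- ancestor_closure(dag)
  anc <- unique(unlist(closure[terms], use.names = FALSE))
  if (include_self) anc <- unique(c(terms, anc))
  anc
}

# memoised per-term ancestor sets (excluding self), computed in topo order
ancestor_closure <- function(dag) {
  cache <- attr(dag, "anc_cache")
  if (!is.null(cache)) return(cache)
  closure <- vector("list", length(dag$terms))
  names(closure) <- dag$terms
  done <- setNames(logical(length(dag$terms)), dag$terms)
  visit <- function(t) {
    if (done[[t]]) return(closure[[t]])
    par <- dag$parents[[t]]
    anc <- par
    for (p in par) anc <- c(anc, visit(p))
    closure[[t]] <<- unique(anc)
    done[[t]] <<- TRUE
    closure[[t]]
  }
  for (t in dag$terms) visit(t)
  closure
}

#' Read a GO annotation table
#'
#' Reads a GAF-like TSV with columns `protein_id`, `term_id`,
#' `evidence_code` and optionally `aspect` (`BP`/`CC`/`MF`). When an ontology
#' is supplied the aspect is taken from the term's namespace, overriding the
#' file. Evidence codes are uppercased and duplicate rows removed.
#'
#' @param path Path to the TSV file.
#' @param ontology Optional `ontology_dag` used to resolve aspects and detect
#'   unknown terms.
#' @param unknown_terms What to do with rows whose term is absent from the
#'   ontology: `"drop"` (default, counted in a message) or `"keep"`.
#' @return data.frame with columns `protein_id`, `term_id`, `aspect`,
#'   `evidence_code`.
#' @export
read_annotations <- function(path, ontology = NULL,
                             unknown_terms = c("drop", "keep")) {
  unknown_terms <- match.arg(unknown_terms)
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    warning("empty annotation table: ", path)
    return(data.frame(protein_id = character(0), term_id = character(0),
                      aspect = character(0), evidence_code = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- split_tsv(tl$lines, tl$lineno, 3L, "annotation")
  df <- data.frame(
    protein_id = vapply(fields, `[`, "", 1L),
    term_id = vapply(fields, `[`, "", 2L),
    evidence_code = toupper(vapply(fields, `[`, "", 3L)),
    aspect = vapply(fields, function(f) {
      if (length(f) >= 4L) f[[4L]] else NA_character_
    }, ""),
    stringsAsFactors = FALSE
  )
  if (!is.null(ontology)) {
    known <- df$term_id %in% ontology$terms
    if (any(!known)) {
      if (unknown_terms == "drop") {
        message("dropped ", sum(!known), " annotation row(s) with terms ",
                "absent from the ontology")
        df <- df[known, , drop = FALSE]
      }
    }
    hit <- match(df$term_id, ontology$terms)
    ns <- unname(ontology$namespace[ontology$terms[hit]])
    df$aspect <- ifelse(is.na(hit), df$aspect, ns)
  }
  df <- df[!duplicated(df[c("protein_id", "term_id", "evidence_code")]), ,
           drop = FALSE]
  rownames(df) <- NULL
  df[c("protein_id", "term_id", "aspect", "evidence_code")]
}

#' Read an expression matrix TSV
#'
#' First column holds gene ids, the header row holds sample ids, remaining
#' cells are numeric expression values.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression matrix needs >= 1 sample column")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression matrix")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ids in expression matrix")
  }
  rownames(m) <- genes
  m
}

#' Write an expression matrix TSV
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a complex membership table (complex_id, protein_id)
#'
#' @param path Path to a two-column TSV.
#' @return Named list: complex_id -> character vector of member proteins.
#' @export
read_complex_table <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) return(list())
  fields <- split_tsv(tl$lines, tl$lineno, 2L, "complex membership")
  cx <- vapply(fields, `[`, "", 1L)
  pr <- vapply(fields, `[`, "", 2L)
  lapply(split(pr, cx), unique)
}

#' Read an ortholog map (source_protein, target_protein)
#'
#' @param path Path to a two-column TSV.
#' @param organism Organism label attached to the map.
#' @return An `ortholog_map`: list with `organism` and `mapping` (named list
#'   source -> character vector of targets).
#' @export
read_ortholog_map <- function(path, organism = NA_character_) {
  tl <- read_tsv_lines(path)
  mapping <- list()
  if (length(tl$lines)) {
    fields <- split_tsv(tl$lines, tl$lineno, 2L, "ortholog map")
    src <- vapply(fields, `[`, "", 1L)
    tgt <- vapply(fields, `[`, "", 2L)
    mapping <- lapply(split(tgt, src), unique)
  }
  structure(list(organism = organism, mapping = mapping),
            class = "ortholog_map")
}

#' Read a protein-to-domain table (protein_id, domain_id)
#'
#' @param path Path to a two-column TSV.
#' @return Named list: protein_id -> character vector of domain ids.
#' @export
read_domain_table <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) return(list())
  fields <- split_tsv(tl$lines, tl$lineno, 2L, "domain table")
  pr <- vapply(fields, `[`, "", 1L)
  dm <- vapply(fields, `[`, "", 2L)
  lapply(split(dm, pr), unique)
}

#' Read a gene-context table
#'
#' Columns: genome_id, gene_id, contig, start, end, strand, and optionally a
#' seventh column linking the gene to a query-proteome protein id.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `genome`, `gene`, `contig`, `start`,
#'   `end`, `strand`, `query_protein` (NA when absent).
#' @export
read_gene_context <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    return(data.frame(genome = character(0), gene = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      query_protein = character(0), stringsAsFactors = FALSE))
  }
  fields <- split_tsv(tl$lines, tl$lineno, 6L, "gene context")
  df <- data.frame(
    genome = vapply(fields, `[`, "", 1L),
    gene = vapply(fields, `[`, "", 2L),
    contig = vapply(fields, `[`, "", 3L),
    start = as.integer(vapply(fields, `[`, "", 4L)),
    end = as.integer(vapply(fields, `[`, "", 5L)),
    strand = vapply(fields, `[`, "", 6L),
    query_protein = vapply(fields, function(f) {
      if (length(f) >= 7L) f[[7L]] else NA_character_
    }, ""),
    stringsAsFactors = FALSE
  )
  if (any(df$start > df$end)) stop("gene context row with start > end")
  if (any(df$start <= 0L)) stop("gene context coordinates must be positive")
  df
}

#' Write a scored network to TSV or SIF
#'
#' The TSV format carries one column per evidence LR plus `lr_functional`,
#' `lr_total`, `posterior_odds` and `tier`; numbers are written with enough
#' digits that a read-back reproduces the network. SIF emits
#' `protein_a pp protein_b` lines only.
#'
#' @param network A `scored_network` data.frame from [assign_tiers()].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @export
write_network <- function(network, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- paste(network$protein_a, "pp", network$protein_b)
    writeLines(lines, path)
    return(invisible(path))
  }
  df <- as.data.frame(network)
  df$key <- NULL
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- format_sig(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_sig <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  trimws(out)
}

#' Read back a scored network TSV written by [write_network()]
#'
#' @param path Path to the TSV.
#' @return A `scored_network` data.frame.
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df)) {
    df$key <- pair_key(df$protein_a, df$protein_b)
  } else {
    df$key <- character(0)
  }
  class(df) <- c("scored_network", "data.frame")
  df
}
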