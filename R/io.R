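#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of probe ids, an
#' optional second column `gene` of gene symbols, and one probe per row of
#' linear-scale intensities. Alternatively the probe-to-gene map can be
#' supplied as a separate two-column TSV (`probe_id`, `gene`). Probes with no
#' gene mapping keep `NA` and are ignored by gene-level operations.
#'
#' @param path Path to the expression TSV.
#' @param gene_map_path Optional path to a two-column probe/gene TSV.
#' @return An expression tibble (see [as_expression_tbl()]).
#' @export
read_expression_tsv <- function(path, gene_map_path = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) abort(sprintf("Empty expression file: %s", path))
  names(raw)[1] <- "probe_id"
  if (ncol(raw) >= 2 && names(raw)[2] == "gene") {
    smp <- names(raw)[-(1:2)]
  } else {
    raw$gene <- NA_character_
    smp <- setdiff(names(raw), c("probe_id", "gene"))
  }
  for (s in smp) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(v) & !is.na(raw[[s]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value '%s' at probe '%s', column '%s' in %s.",
                    raw[[s]][bad[1]], raw$probe_id[bad[1]], s, path))
    }
    if (anyNA(v)) {
      abort(sprintf("Missing intensity at probe '%s', column '%s' in %s.",
                    raw$probe_id[which(is.na(v))[1]], s, path))
    }
    raw[[s]] <- v
  }
  x <- as_expression_tbl(raw)
  if (!is.null(gene_map_path)) {
    map <- readr::read_tsv(gene_map_path,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (ncol(map) < 2) abort("Probe-gene map must have two columns.")
    names(map)[1:2] <- c("probe_id", "gene")
    x$gene <- map$gene[match(x$probe_id, map$probe_id)]
  }
  check_nonnegative_intensities(x)
  x
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_tsv()]: `probe_id`, `gene`, then one column per
#' sample. Unmapped genes are written as empty strings and read back as `NA`.
#'
#' @param x An expression tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  x <- as_expression_tbl(x)
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(x)
}

#' Gene-set collections
#'
#' Gene sets (GO terms, KEGG pathways, custom signatures) are held in a long
#' tibble with columns `set_id`, `set_name` and `gene` — one row per
#' membership, in the style of over-representation tools that take a
#' term-to-gene table. Within a set, gene symbols are unique; matching is by
#' exact case-sensitive symbol.
#'
#' @param x A data frame with columns `set_id`, `gene` and optionally
#'   `set_name`.
#' @return A validated, deduplicated gene-set tibble.
#' @export
as_geneset_tbl <- function(x) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  x <- as_tibble(x)
  if (!all(c("set_id", "gene") %in% names(x))) {
    abort("Gene-set table needs `set_id` and `gene` columns.")
  }
  if (!"set_name" %in% names(x)) x$set_name <- x$set_id
  x <- dplyr::distinct(x[, c("set_id", "set_name", "gene")],
                       .data$set_id, .data$gene, .keep_all = TRUE)
  if (any(x$set_id == "" | is.na(x$set_id))) abort("Empty set_id.")
  if (any(x$gene == "" | is.na(x$gene))) abort("Empty gene symbol in a gene set.")
  nm <- dplyr::distinct(x[, c("set_id", "set_name")])
  if (anyDuplicated(nm$set_id)) abort("A set_id maps to two different names.")
  x
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description, then
#' gene symbols. Repeated symbols within a line count once.
#'
#' @param path Path to the GMT file.
#' @return A gene-set tibble (empty for an empty file).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(as_tibble(data.frame(set_id = character(), set_name = character(),
                                gene = character())))
  }
  rows <- purrr::imap(lines, function(l, i) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("GMT line %d has %d field(s); at least 3 required.", i, length(f)))
    }
    tibble(set_id = f[1], set_name = f[2], gene = unique(f[-(1:2)]))
  })
  as_geneset_tbl(dplyr::bind_rows(rows))
}

#' Write a gene-set collection as GMT
#'
#' @param sets A gene-set tibble.
#' @param path Output path.
#' @return `sets`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  sets <- as_geneset_tbl(sets)
  by_set <- split(sets, factor(sets$set_id, levels = unique(sets$set_id)))
  lines <- vapply(by_set, function(s) {
    paste(c(s$set_id[1], s$set_name[1], s$gene), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(sets)
}

#' Read NCBI gene2go annotations as a gene-set collection
#'
#' Parses the NCBI gene2go dialect (tab-separated `tax_id`, `GeneID`, `GO_ID`,
#' `Evidence`, `Qualifier`, `GO_term`, `PubMed`, `Category`; `#` lines are
#' comments), keeping rows for one taxon and grouping genes by GO id. Rows
#' whose qualifier contains `NOT` assert the gene does *not* have the
#' annotation and are excluded. Malformed rows are skipped with a warning
#' reporting the count.
#'
#' @param path Path to a gene2go-format TSV.
#' @param tax_id NCBI taxonomy id to keep (9606 for human).
#' @return A gene-set tibble; `set_name` is the GO term text.
#' @export
read_gene2go <- function(path, tax_id = 9606) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 8
  if (any(!ok)) {
    warn(sprintf("Skipped %d malformed gene2go row(s).", sum(!ok)))
    fields <- fields[ok]
  }
  if (length(fields) == 0) {
    return(as_tibble(data.frame(set_id = character(), set_name = character(),
                                gene = character())))
  }
  tab <- tibble(
    tax = vapply(fields, `[[`, character(1), 1),
    gene = vapply(fields, `[[`, character(1), 2),
    set_id = vapply(fields, `[[`, character(1), 3),
    qualifier = vapply(fields, `[[`, character(1), 5),
    set_name = vapply(fields, `[[`, character(1), 6)
  )
  tab <- tab[tab$tax == as.character(tax_id) & !grepl("NOT", tab$qualifier), ]
  if (nrow(tab) == 0) {
    return(as_tibble(data.frame(set_id = character(), set_name = character(),
                                gene = character())))
  }
  as_geneset_tbl(tab[, c("set_id", "set_name", "gene")])
}

#' Read a flat KEGG pathway gene list
#'
#' Simple two-column dialect: each line `pathway_id <TAB> gene_symbol`. Lines
#' may interleave pathways freely.
#'
#' @param path Path to the flat TSV.
#' @return A gene-set tibble.
#' @export
read_kegg_gene_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(as_tibble(data.frame(set_id = character(), set_name = character(),
                                gene = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(sprintf("KEGG list line %d has fewer than 2 fields.", bad[1]))
  }
  as_geneset_tbl(tibble(
    set_id = vapply(fields, `[[`, character(1), 1),
    gene = vapply(fields, `[[`, character(1), 2)
  ))
}

#' Read / write a sample grouping TSV
#'
#' Columns `sample_id`, `group` (1 or 2) and optionally `subgroup`. Accepted
#' wherever a grouping is needed, bypassing clustering (e.g. a
#' histology-defined split).
#'
#' @param path File path.
#' @return A grouping tibble.
#' @export
read_grouping_tsv <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), group = readr::col_integer(),
    .default = readr::col_character()
  ), progress = FALSE)
  as_grouping_tbl(g)
}

#' @rdname read_grouping_tsv
#' @param grouping A grouping tibble.
#' @export
write_grouping_tsv <- function(grouping, path) {
  readr::write_tsv(as_grouping_tbl(grouping), path, progress = FALSE)
  invisible(grouping)
}

#' Write a result table to TSV with deterministic ordering
#'
#' Rows are ordered by ascending p-value, ties broken by the identifier
#' column (`set_id`, `gene` or `probe_id`, whichever the result carries)
#' in lexicographic order. Column order is preserved as produced by the
#' analysis functions.
#'
#' @param results A result tibble from [cafet_groups()], [cafet_genes()],
#'   [fga_enrich()] or [differential_expression()].
#' @param path Output path.
#' @return The ordered tibble, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  if (!is.data.frame(results)) abort("`results` must be a data frame.")
  key <- intersect(c("set_id", "gene", "probe_id"), names(results))
  if (nrow(results) > 0 && "p_value" %in% names(results)) {
    ord <- order(results$p_value,
                 if (length(key) > 0) results[[key[1]]] else seq_len(nrow(results)),
                 method = "radix")
    results <- results[ord, , drop = FALSE]
  }
  readr::write_tsv(results, path, progress = FALSE)
  invisible(results)
}

#' Read a signature definition TSV
#'
#' Two columns: `gene` and `direction` (`up` or `down`).
#'
#' @param path File path.
#' @return A tibble with columns `gene`, `direction`.
#' @export
read_signature_tsv <- function(path) {
  s <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!all(c("gene", "direction") %in% names(s))) {
    abort("Signature file needs `gene` and `direction` columns.")
  }
  if (!all(s$direction %in% c("up", "down"))) {
    abort("Signature `direction` must be 'up' or 'down'.")
  }
  s[, c("gene", "direction")]
}
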