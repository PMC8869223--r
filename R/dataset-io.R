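#' Expression study container
#'
#' A minimal container for one study's normalized expression data: a numeric
#' feature-by-sample matrix with feature and sample identifiers, the scale the
#' values are on, and the measurement platform. Linear-scale RNA-seq style
#' input (RPKM-like) is expected to be converted to `log2(x + 1)` at read time
#' by [read_expression()].
#'
#' @param study_id Accession-like study identifier.
#' @param matrix Numeric matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param scale `"log2"` or `"linear"`.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(study_id, matrix, scale = c("log2", "linear"),
                             platform = c("microarray", "rnaseq")) {
  scale <- match.arg(scale)
  platform <- match.arg(platform)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    hep_stop("format", "expression matrix must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    hep_stop("format", "expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(colnames(matrix)))
    hep_stop("format", "duplicate sample id: %s",
             colnames(matrix)[duplicated(colnames(matrix))][1L])
  if (anyDuplicated(rownames(matrix)))
    hep_stop("format", "duplicate feature id: %s",
             rownames(matrix)[duplicated(rownames(matrix))][1L])
  all_na <- rowSums(!is.na(matrix)) == 0L
  if (any(all_na))
    hep_stop("format", "feature '%s' has no non-missing values",
             rownames(matrix)[all_na][1L])
  structure(
    list(study_id = study_id, matrix = matrix, scale = scale,
         platform = platform),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s: %d features x %d samples [%s, %s]\n",
              x$study_id, nrow(x$matrix), ncol(x$matrix), x$platform, x$scale))
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' First column holds feature ids, the header holds sample ids. Linear-scale
#' values with `platform = "rnaseq"` are transformed to `log2(x + 1)`;
#' values declared `scale = "log2"` pass through unchanged.
#'
#' @param path TSV file path.
#' @param study_id Study identifier (defaults to the file name).
#' @param scale Scale of the values in the file.
#' @param platform Measurement platform.
#' @return An [expression_study()].
#' @export
read_expression <- function(path, study_id = basename(path),
                            scale = c("log2", "linear"),
                            platform = c("microarray", "rnaseq")) {
  scale <- match.arg(scale)
  platform <- match.arg(platform)
  if (!file.exists(path)) hep_stop("format", "file not found: %s", path)
  df <- tryCatch(read_tsv(path),
                 error = function(e) hep_stop("format", "cannot parse %s: %s",
                                              path, conditionMessage(e)))
  if (ncol(df) < 2L) hep_stop("format", "%s: need a feature column plus samples", path)
  header <- names(df)[-1L]
  if (anyDuplicated(header))
    hep_stop("format", "%s: duplicate sample id '%s'", path,
             header[duplicated(header)][1L])
  feats <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1L))
  if (any(bad))
    hep_stop("format", "%s: non-numeric values in sample column '%s'",
             path, names(vals)[bad][1L])
  m <- as.matrix(vals)
  rownames(m) <- feats
  if (scale == "linear" && platform == "rnaseq") {
    if (any(m < 0, na.rm = TRUE))
      hep_stop("format", "%s: negative values on linear scale", path)
    m <- log2(m + 1)
    scale <- "log2"
  }
  expression_study(study_id, m, scale = scale, platform = platform)
}

#' Write an expression study as TSV
#'
#' Inverse of [read_expression()] for log2-scale studies; the round trip is
#' exact on the text representation.
#'
#' @param study An [expression_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(study, path) {
  df <- data.frame(gene = rownames(study$matrix), study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Collapse probe-level features to genes
#'
#' Among multiple probes mapping to one gene, the probe with the highest mean
#' expression across all samples is retained (ties broken by lexicographically
#' smallest probe id). Features absent from the map are dropped.
#'
#' @param study An [expression_study()].
#' @param feature_to_gene Named character vector: names are feature ids,
#'   values are gene ids.
#' @return An [expression_study()] with one row per gene; attribute
#'   `n_dropped` records the number of unmapped features removed.
#' @export
collapse_features <- function(study, feature_to_gene) {
  if (length(feature_to_gene) == 0L)
    hep_stop("processing", "empty feature-to-gene map")
  feats <- rownames(study$matrix)
  mapped <- intersect(feats, names(feature_to_gene))
  if (length(mapped) == 0L)
    hep_stop("processing", "no features of study '%s' are covered by the map",
             study$study_id)
  n_dropped <- length(feats) - length(mapped)
  m <- study$matrix[mapped, , drop = FALSE]
  gene <- unname(feature_to_gene[mapped])
  means <- rowMeans(m, na.rm = TRUE)
  # order: by gene, then decreasing mean, then probe id; keep first per gene
  ord <- order(gene, -means, mapped, method = "radix")
  keep <- ord[!duplicated(gene[ord])]
  out <- m[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  out <- out[order(rownames(out)), , drop = FALSE]
  res <- expression_study(study$study_id, out, scale = study$scale,
                          platform = study$platform)
  attr(res, "n_dropped") <- n_dropped
  res
}

diet_codes <- c("CC", "CO", "OC", "OO")

#' Comparison specification
#'
#' One two-group comparison within a study, in the maternal/offspring diet
#' coding of the field (first letter mother's diet, second the offspring's;
#' C control, O obesogenic).
#'
#' @param comparison_id Identifier, e.g. `"GSE44901_CCvsOC"`.
#' @param study_id Study (series) identifier.
#' @param group_a_samples,group_b_samples Disjoint sample-id vectors, each of
#'   size >= 2. Log fold changes downstream are group B minus group A.
#' @param offspring_sex `"M"`, `"F"` or `NA`.
#' @param offspring_age_weeks Age in weeks, or `NA`.
#' @param diet_code_a,diet_code_b Diet codes, one of CC/CO/OC/OO, unequal.
#' @return An object of class `comparison_spec`.
#' @export
comparison_spec <- function(comparison_id, study_id,
                            group_a_samples, group_b_samples,
                            offspring_sex = NA_character_,
                            offspring_age_weeks = NA_real_,
                            diet_code_a = "CC", diet_code_b = "OC") {
  group_a_samples <- as.character(group_a_samples)
  group_b_samples <- as.character(group_b_samples)
  if (length(group_a_samples) < 2L || length(group_b_samples) < 2L)
    hep_stop("config", "comparison '%s': each group needs >= 2 samples",
             comparison_id)
  if (length(intersect(group_a_samples, group_b_samples)) > 0L)
    hep_stop("config", "comparison '%s': groups overlap (%s)", comparison_id,
             intersect(group_a_samples, group_b_samples)[1L])
  if (!diet_code_a %in% diet_codes || !diet_code_b %in% diet_codes)
    hep_stop("config", "comparison '%s': diet codes must be one of %s",
             comparison_id, paste(diet_codes, collapse = "/"))
  if (identical(diet_code_a, diet_code_b))
    hep_stop("config", "comparison '%s': diet codes must differ", comparison_id)
  if (!is.na(offspring_sex) && !offspring_sex %in% c("M", "F"))
    hep_stop("config", "comparison '%s': offspring_sex must be M, F or NA",
             comparison_id)
  structure(
    list(comparison_id = comparison_id, study_id = study_id,
         group_a_samples = group_a_samples, group_b_samples = group_b_samples,
         offspring_sex = offspring_sex,
         offspring_age_weeks = offspring_age_weeks,
         diet_code_a = diet_code_a, diet_code_b = diet_code_b),
    class = "comparison_spec"
  )
}

#' Read a comparison configuration (YAML or JSON)
#'
#' The file holds a top-level `comparisons` list; each entry carries
#' `comparison_id`, `study_id`, `group_a_samples`, `group_b_samples` and
#' optionally `offspring_sex`, `offspring_age_weeks`, `diet_code_a`,
#' `diet_code_b`. Group invariants are validated; when `studies` are supplied
#' the sample ids are checked against them.
#'
#' @param path Config file; format picked by extension (`.yaml`/`.yml` vs
#'   `.json`).
#' @param studies Optional list of [expression_study()] objects, keyed or not,
#'   used to verify that every referenced sample exists.
#' @return List of [comparison_spec()] objects, ordered as in the file, with
#'   attribute `by_study` grouping comparison ids by study id.
#' @export
read_comparisons <- function(path, studies = NULL) {
  if (!file.exists(path)) hep_stop("config", "config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  entries <- raw[["comparisons"]]
  if (is.null(entries) || length(entries) == 0L)
    hep_stop("config", "%s: no 'comparisons' entries", path)
  specs <- lapply(entries, function(e) {
    comparison_spec(
      comparison_id = e$comparison_id, study_id = e$study_id,
      group_a_samples = unlist(e$group_a_samples),
      group_b_samples = unlist(e$group_b_samples),
      offspring_sex = if (is.null(e$offspring_sex)) NA_character_ else e$offspring_sex,
      offspring_age_weeks = if (is.null(e$offspring_age_weeks)) NA_real_
                            else as.numeric(e$offspring_age_weeks),
      diet_code_a = if (is.null(e$diet_code_a)) "CC" else e$diet_code_a,
      diet_code_b = if (is.null(e$diet_code_b)) "OC" else e$diet_code_b
    )
  })
  ids <- vapply(specs, `[[`, "", "comparison_id")
  if (anyDuplicated(ids))
    hep_stop("config", "duplicate comparison_id: %s", ids[duplicated(ids)][1L])
  if (!is.null(studies)) {
    samp <- lapply(studies, function(s) colnames(s$matrix))
    names(samp) <- vapply(studies, `[[`, "", "study_id")
    for (sp in specs) {
      if (!sp$study_id %in% names(samp))
        hep_stop("config", "comparison '%s': unknown study '%s'",
                 sp$comparison_id, sp$study_id)
      missing <- setdiff(c(sp$group_a_samples, sp$group_b_samples),
                         samp[[sp$study_id]])
      if (length(missing) > 0L)
        hep_stop("config", "comparison '%s': sample '%s' not in study '%s'",
                 sp$comparison_id, missing[1L], sp$study_id)
    }
  }
  by_study <- split(ids, vapply(specs, `[[`, "", "study_id"))
  names(specs) <- ids
  attr(specs, "by_study") <- by_study
  specs
}

#' Gene-set collection
#'
#' @param sets Named list of character vectors of member gene ids; names are
#'   pathway ids.
#' @param names_ Optional character vector of human-readable set names
#'   (descriptions), parallel to `sets`.
#' @param universe Annotation universe. Defaults to the union of all members.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, names_ = NULL, universe = NULL) {
  if (length(sets) == 0L) hep_stop("format", "gene-set collection is empty")
  if (is.null(names(sets)) || any(names(sets) == ""))
    hep_stop("format", "every gene set needs a pathway id")
  empty <- vapply(sets, function(g) length(g) == 0L || any(!nzchar(g)), TRUE)
  if (any(empty))
    hep_stop("format", "gene set '%s' has empty member ids",
             names(sets)[empty][1L])
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (is.null(names_)) names_ <- names(sets)
  structure(list(sets = sets, set_names = names_, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT file
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated. On duplicate set ids the later line wins (with a warning).
#'
#' @param path GMT file.
#' @param universe Optional path to a one-gene-per-line universe file; when
#'   absent the universe is the union of all members.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) hep_stop("format", "GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) hep_stop("format", "%s: empty GMT file", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    hep_stop("format", "%s: line %d has %d fields (need >= 3)",
             path, which(nf < 3L)[1L], nf[nf < 3L][1L])
  ids <- vapply(parts, `[[`, "", 1L)
  descs <- vapply(parts, `[[`, "", 2L)
  members <- lapply(parts, function(p) unique(p[-(1:2)]))
  if (anyDuplicated(ids)) {
    hep_warn("duplicate pathway id(s) in %s: %s (later line wins)", path,
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    keep <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[keep]; descs <- descs[keep]; members <- members[keep]
  }
  names(members) <- ids
  uni <- if (!is.null(universe)) readLines(universe) else NULL
  gene_set_collection(members, names_ = descs, universe = uni)
}

#' Write a gene-set collection as GMT
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], collection$set_names[i],
            collection$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a genes-of-interest list
#'
#' Plain text, one gene per line; an optional tab-separated second column is a
#' free-text source note. Gene ids are case-sensitive symbols and must be
#' unique.
#'
#' @param path File path.
#' @return Data frame with columns `gene` and `note`.
#' @export
read_genes_of_interest <- function(path) {
  if (!file.exists(path)) hep_stop("config", "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) hep_stop("config", "%s: no genes listed", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(parts, `[[`, "", 1L)
  notes <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", "")
  if (anyDuplicated(genes))
    hep_stop("config", "%s: duplicate gene '%s'", path,
             genes[duplicated(genes)][1L])
  data.frame(gene = genes, note = notes, stringsAsFactors = FALSE)
}
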