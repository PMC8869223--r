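# Synthetic multi-study cohorts with planted ground truth. The generator is
# the test bed for every downstream stage: differential expression, consensus
# selection, pathway enrichment and histology quantification all have a known
# answer on its output.

#' Simulation design for a synthetic multi-study cohort
#'
#' Describes a set of independent two-group expression "studies" (each
#' contributing one or more comparisons), a set of planted consensus genes
#' with known log2 fold changes, and planted pathway enrichments. Gene-wise
#' residual variances are drawn from a scaled inverse-chi-squared prior with
#' parameters `(d0, s0_sq)`, matching the empirical-Bayes model the
#' differential-expression stage assumes.
#'
#' @param n_studies Number of independent studies.
#' @param comparisons_per_study Two-group comparisons per study.
#' @param n_genes Genes per study.
#' @param n_samples_per_group Samples in each of the two groups of every
#'   comparison.
#' @param planted_genes `NULL`, or a data frame with columns `gene` (gene id,
#'   or `NA` to let the generator pick), `logfc` (true log2 fold change
#'   applied to group B) and `n_comparisons` (number of comparisons carrying
#'   the effect).
#' @param planted_pathways `NULL`, or a list of lists with elements
#'   `pathway_id`, `members` (gene ids, or a single integer size to let the
#'   generator pick), `affected_fraction` (fraction of members perturbed),
#'   `direction` (`"up"` or `"down"`), `logfc` (effect magnitude, default 1)
#'   and `n_comparisons` (comparisons carrying the enrichment, default 4).
#' @param variance_prior Length-2 numeric `c(d0, s0_sq)`: prior degrees of
#'   freedom and prior variance of the scaled inverse-chi-squared law for
#'   gene-wise residual variances (log2 units squared).
#' @param noise_sd_floor Lower bound on the per-gene residual standard
#'   deviation, log2 units.
#' @param baseline_mean,baseline_sd Mean and spread of gene baseline log2
#'   expression.
#' @param seed Integer seed; every artifact is a pure function of
#'   `(design, seed)` via named substreams.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_studies = 5L, comparisons_per_study = 2L,
                              n_genes = 2000L, n_samples_per_group = 8L,
                              planted_genes = NULL, planted_pathways = NULL,
                              variance_prior = c(d0 = 16, s0_sq = 0.0025),
                              noise_sd_floor = 0.01,
                              baseline_mean = 7, baseline_sd = 1,
                              seed = 1L) {
  n_comp <- n_studies * comparisons_per_study
  if (n_studies < 1L || comparisons_per_study < 1L || n_genes < 1L)
    hep_stop("config", "n_studies, comparisons_per_study and n_genes must be >= 1")
  if (n_samples_per_group < 2L)
    hep_stop("config", "n_samples_per_group must be >= 2")
  d0 <- unname(variance_prior[1L]); s0_sq <- unname(variance_prior[2L])
  if (!(d0 > 0) || !(s0_sq > 0))
    hep_stop("config", "variance prior requires d0 > 0 and s0_sq > 0")
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  if (!is.null(planted_genes)) {
    planted_genes <- as.data.frame(planted_genes)
    need <- c("gene", "logfc", "n_comparisons")
    if (!all(need %in% names(planted_genes)))
      hep_stop("config", "planted_genes needs columns %s",
               paste(need, collapse = ", "))
    if (any(planted_genes$n_comparisons > n_comp))
      hep_stop("config",
               "planted gene affects %d comparisons but only %d exist",
               max(planted_genes$n_comparisons), n_comp)
    known <- planted_genes$gene[!is.na(planted_genes$gene)]
    if (length(setdiff(known, gene_ids)) > 0L)
      hep_stop("config", "planted gene id '%s' not among the %d genes",
               setdiff(known, gene_ids)[1L], n_genes)
    if (anyDuplicated(known))
      hep_stop("config", "duplicate planted gene id")
  }
  if (!is.null(planted_pathways)) {
    for (pw in planted_pathways) {
      if (is.null(pw$pathway_id) || is.null(pw$members))
        hep_stop("config", "each planted pathway needs pathway_id and members")
      if (is.character(pw$members) &&
          length(setdiff(pw$members, gene_ids)) > 0L)
        hep_stop("config", "pathway '%s' member '%s' not among the genes",
                 pw$pathway_id, setdiff(pw$members, gene_ids)[1L])
      frac <- if (is.null(pw$affected_fraction)) 0.5 else pw$affected_fraction
      if (frac < 0 || frac > 1)
        hep_stop("config", "pathway '%s': affected_fraction outside [0,1]",
                 pw$pathway_id)
      dir <- if (is.null(pw$direction)) "up" else pw$direction
      if (!dir %in% c("up", "down"))
        hep_stop("config", "pathway '%s': direction must be up or down",
                 pw$pathway_id)
      nc <- if (is.null(pw$n_comparisons)) 4L else pw$n_comparisons
      if (nc > n_comp)
        hep_stop("config", "pathway '%s' affects %d comparisons but only %d exist",
                 pw$pathway_id, nc, n_comp)
    }
  }
  structure(
    list(n_studies = as.integer(n_studies),
         comparisons_per_study = as.integer(comparisons_per_study),
         n_genes = as.integer(n_genes),
         n_samples_per_group = as.integer(n_samples_per_group),
         gene_ids = gene_ids,
         planted_genes = planted_genes,
         planted_pathways = planted_pathways,
         d0 = d0, s0_sq = s0_sq,
         noise_sd_floor = noise_sd_floor,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(paste0("<simulation_design> %d studies x %d comparisons, ",
                     "%d genes, n=%d/group, d0=%g, s0^2=%g, seed=%d\n"),
              x$n_studies, x$comparisons_per_study, x$n_genes,
              x$n_samples_per_group, x$d0, x$s0_sq, x$seed))
  invisible(x)
}

# layout of comparisons implied by a design: diet pairs alternate between the
# CC-vs-OC (both generations on control food, mother obesogenic in B) and the
# CO-vs-OO contrast, mirroring the two-comparisons-per-series structure of the
# real cohort table.
design_comparisons <- function(design) {
  out <- list()
  for (i in seq_len(design$n_studies)) {
    study_id <- sprintf("SYN%02d", i)
    for (j in seq_len(design$comparisons_per_study)) {
      pair <- if (j %% 2L == 1L) c("CC", "OC") else c("CO", "OO")
      comp_id <- sprintf("%s_%svs%s_c%d", study_id, pair[1L], pair[2L], j)
      n <- design$n_samples_per_group
      out[[comp_id]] <- comparison_spec(
        comparison_id = comp_id, study_id = study_id,
        group_a_samples = sprintf("%s_A%02d", comp_id, seq_len(n)),
        group_b_samples = sprintf("%s_B%02d", comp_id, seq_len(n)),
        offspring_sex = "M", offspring_age_weeks = 12,
        diet_code_a = pair[1L], diet_code_b = pair[2L]
      )
    }
  }
  out
}

# Resolve planted genes / pathway memberships and build the gene x comparison
# matrix of true log2 fold changes. Runs in its own dedicated substream so
# the expression and GMT artifacts agree on the same resolved truth.
resolve_truth <- function(design) {
  with_seed(substream_seed(design$seed, "truth"), resolve_truth_impl(design))
}

resolve_truth_impl <- function(design) {
  comps <- design_comparisons(design)
  comp_ids <- names(comps)
  genes <- design$gene_ids
  lfc <- matrix(0, nrow = design$n_genes, ncol = length(comp_ids),
                dimnames = list(genes, comp_ids))

  pg <- design$planted_genes
  if (!is.null(pg) && nrow(pg) > 0L) {
    free <- setdiff(genes, pg$gene[!is.na(pg$gene)])
    need <- sum(is.na(pg$gene))
    if (need > 0L) pg$gene[is.na(pg$gene)] <- sample(free, need)
    for (r in seq_len(nrow(pg))) {
      affected <- sample(comp_ids, pg$n_comparisons[r])
      lfc[pg$gene[r], affected] <- pg$logfc[r]
    }
  }

  pw_resolved <- list()
  if (!is.null(design$planted_pathways)) {
    reserved <- if (is.null(pg)) character() else pg$gene
    for (pw in design$planted_pathways) {
      members <- pw$members
      if (is.numeric(members) && length(members) == 1L) {
        pool <- setdiff(genes, c(reserved, unlist(lapply(pw_resolved,
                                                         `[[`, "members"))))
        if (length(pool) < members)
          hep_stop("config", "not enough free genes for pathway '%s'",
                   pw$pathway_id)
        members <- sample(pool, members)
      }
      frac <- if (is.null(pw$affected_fraction)) 0.5 else pw$affected_fraction
      dir <- if (is.null(pw$direction)) "up" else pw$direction
      mag <- if (is.null(pw$logfc)) 1.0 else pw$logfc
      nc <- if (is.null(pw$n_comparisons)) 4L else pw$n_comparisons
      n_aff <- ceiling(frac * length(members))
      affected_genes <- if (n_aff > 0L) sample(members, n_aff) else character()
      affected_comps <- sample(comp_ids, nc)
      signed <- if (dir == "up") abs(mag) else -abs(mag)
      lfc[affected_genes, affected_comps] <- signed
      pw_resolved[[pw$pathway_id]] <- list(
        pathway_id = pw$pathway_id, members = members,
        affected_genes = affected_genes, affected_comps = affected_comps,
        direction = dir, logfc = signed
      )
    }
  }

  # expected-consensus ids: planted genes (including pathway-affected ones)
  # whose affected comparisons satisfy the replication rule (>= 3
  # comparisons, or >= 2 distinct studies)
  study_of <- vapply(comps, `[[`, "", "study_id")
  planted_any <- rownames(lfc)[rowSums(lfc != 0) > 0L]
  consensus_ids <- Filter(function(g) {
    hit <- comp_ids[lfc[g, ] != 0]
    length(hit) >= 3L || length(unique(study_of[hit])) >= 2L
  }, planted_any)
  consensus_ids <- as.character(consensus_ids)

  list(comparisons = comps, true_logfc = lfc, planted_genes = pg,
       pathways = pw_resolved, consensus_gene_ids = consensus_ids)
}

#' Generate synthetic expression studies with planted truth
#'
#' Each study's matrix is log2-scale two-group expression: per-gene baselines,
#' gene-wise residual variances drawn from the scaled inverse-chi-squared
#' prior `(d0, s0_sq)` (independently per study), Gaussian noise, and the
#' design's planted log2 fold changes added to group B of the affected
#' comparisons. Regeneration with the same design and seed is byte-identical.
#'
#' @param design A [simulation_design()].
#' @return A list of class `synthetic_cohort`:
#'   \describe{
#'     \item{studies}{named list of [expression_study()] objects}
#'     \item{comparisons}{named list of [comparison_spec()] objects}
#'     \item{truth}{ground truth: `consensus_gene_ids`, `true_logfc`
#'       (gene x comparison matrix), `planted_genes`, `pathways`,
#'       `sigma` (gene x study residual-sd matrix)}
#'   }
#' @export
generate_expression_studies <- function(design) {
  if (!inherits(design, "simulation_design"))
    hep_stop("config", "design must be a simulation_design")
  with_seed(substream_seed(design$seed, "expression"), {
    truth <- resolve_truth(design)
    comps <- truth$comparisons
    study_ids <- unique(vapply(comps, `[[`, "", "study_id"))
    n <- design$n_samples_per_group
    genes <- design$gene_ids
    baseline <- stats::rnorm(design$n_genes, design$baseline_mean,
                             design$baseline_sd)
    sigma <- matrix(NA_real_, design$n_genes, length(study_ids),
                    dimnames = list(genes, study_ids))
    studies <- list()
    for (sid in study_ids) {
      sigma2 <- design$d0 * design$s0_sq /
        stats::rchisq(design$n_genes, df = design$d0)
      sd_g <- pmax(sqrt(sigma2), design$noise_sd_floor)
      sigma[, sid] <- sd_g
      s_comps <- comps[vapply(comps, `[[`, "", "study_id") == sid]
      cols <- unlist(lapply(s_comps, function(cs)
        c(cs$group_a_samples, cs$group_b_samples)), use.names = FALSE)
      m <- matrix(stats::rnorm(design$n_genes * length(cols), sd = 1),
                  design$n_genes, length(cols)) * sd_g + baseline
      dimnames(m) <- list(genes, cols)
      for (cs in s_comps)
        m[, cs$group_b_samples] <- m[, cs$group_b_samples] +
          truth$true_logfc[, cs$comparison_id]
      studies[[sid]] <- expression_study(sid, m, scale = "log2",
                                         platform = "microarray")
    }
    truth$sigma <- sigma
    structure(list(studies = studies, comparisons = comps, truth = truth,
                   design = design),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d studies, %d comparisons, ",
                     "%d genes, %d planted consensus genes, %d planted pathways\n"),
              length(x$studies), length(x$comparisons), x$design$n_genes,
              length(x$truth$consensus_gene_ids), length(x$truth$pathways)))
  invisible(x)
}

#' Generate a gene-set collection matching a design
#'
#' The collection holds every planted pathway (member lists exactly as in the
#' ground truth) plus random background pathways drawn from the design's
#' genes. The universe is the full design gene list, emulating an annotation
#' that covers the array.
#'
#' @param design A [simulation_design()].
#' @param n_background Number of random background pathways.
#' @param size_range Length-2 integer range of background pathway sizes.
#' @return A [gene_set_collection()].
#' @export
generate_gmt <- function(design, n_background = 40L, size_range = c(20L, 80L)) {
  if (!inherits(design, "simulation_design"))
    hep_stop("config", "design must be a simulation_design")
  with_seed(substream_seed(design$seed, "gmt"), {
    truth <- resolve_truth(design)
    sets <- lapply(truth$pathways, `[[`, "members")
    names(sets) <- names(truth$pathways)
    if (n_background > 0L) {
      sizes <- sample(seq(size_range[1L], size_range[2L]), n_background,
                      replace = TRUE)
      bg <- lapply(sizes, function(k) sample(design$gene_ids, k))
      names(bg) <- sprintf("BG%04d", seq_len(n_background))
      sets <- c(sets, bg)
    }
    if (length(sets) == 0L)
      hep_stop("config", "design has no planted pathways and n_background = 0")
    gene_set_collection(sets, universe = design$gene_ids)
  })
}

#' Export a log2 study as linear RPKM-like values
#'
#' Inverse of the `log2(x + 1)` read transform, for exercising the
#' sequencing-reader path on synthetic data.
#'
#' @param study A log2-scale [expression_study()].
#' @return An [expression_study()] on linear scale, platform `rnaseq`.
#' @export
as_linear_rpkm <- function(study) {
  if (study$scale != "log2") hep_stop("config", "study is not on log2 scale")
  m <- 2^study$matrix - 1
  m[m < 0] <- 0
  expression_study(study$study_id, m, scale = "linear", platform = "rnaseq")
}

# ---------------------------------------------------------------------------
# Histology slide generation

# paint an ellipse into a logical mask; returns updated mask or NULL if the
# ellipse leaves `allow` or touches `forbid`
ellipse_pixels <- function(cx, cy, a, b, theta, h, w) {
  r0 <- max(1L, floor(cy - max(a, b))); r1 <- min(h, ceiling(cy + max(a, b)))
  c0 <- max(1L, floor(cx - max(a, b))); c1 <- min(w, ceiling(cx + max(a, b)))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  dx <- outer(rep(1, length(rows)), cols - cx)
  dy <- outer(rows - cy, rep(1, length(cols)))
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  cbind(rows[idx[, 1L]], cols[idx[, 2L]])
}

place_ellipses <- function(target_area, rmin, rmax, ratio_range, allow,
                           forbid, max_attempts = 20000L, what = "vacuole") {
  h <- nrow(allow); w <- ncol(allow)
  mask <- matrix(FALSE, h, w)
  placed <- 0
  min_area <- pi * rmin^2 * ratio_range[1L]
  attempts <- 0L
  allow_idx <- which(allow, arr.ind = TRUE)
  while (target_area - placed >= min_area) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      hep_stop("generation",
               "could not place %s area fraction without overlap (placed %.3f of target)",
               what, placed / target_area)
    remaining <- target_area - placed
    rmax_eff <- min(rmax, sqrt(remaining / (pi * ratio_range[1L])))
    if (rmax_eff < rmin) break
    a <- stats::runif(1, rmin, rmax_eff)
    q <- stats::runif(1, ratio_range[1L], ratio_range[2L])
    b <- a * q
    if (pi * a * b > remaining) next
    theta <- stats::runif(1, 0, pi)
    ctr <- allow_idx[sample.int(nrow(allow_idx), 1L), ]
    px <- ellipse_pixels(ctr[2L], ctr[1L], a, b, theta, h, w)
    if (is.null(px)) next
    ok <- all(allow[px]) && !any(forbid[px]) && !any(mask[px])
    if (!ok) next
    mask[px] <- TRUE
    placed <- placed + nrow(px)
  }
  mask
}

#' Generate a synthetic histology slide with known area fractions
#'
#' Produces an RGB image mimicking a stained liver section: near-white
#' background, eosin-pink tissue, dark hematoxylin-like nuclei, near-white
#' elliptical steatosis vacuoles totalling `vacuole_fraction` of the tissue
#' area (within 1% absolute), and blue-toned fibrosis patches totalling
#' `fibrosis_fraction`. Vacuoles have radius 5-30 px and axis ratio 0.7-1,
#' nuclei radius 2-5 px; vacuole and fibrosis regions never overlap.
#' Ground-truth binary masks are returned alongside the image.
#'
#' @param width,height Image size in pixels.
#' @param vacuole_fraction,fibrosis_fraction Target area fractions of the
#'   tissue region, each in `[0, 0.5]`.
#' @param seed Integer seed; the image is a pure function of the arguments.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @return A list of class `synthetic_slide` with elements `image`
#'   (height x width x 3 array in `[0,1]`), `tissue_mask`, `vacuole_mask`,
#'   `fibrosis_mask`, `nucleus_mask` (logical matrices), and the realized
#'   `vacuole_fraction` / `fibrosis_fraction` (pixel-exact).
#' @export
generate_slide <- function(width = 320L, height = 320L, vacuole_fraction = 0,
                           fibrosis_fraction = 0, seed = 1L,
                           noise_sd = 0.012) {
  if (vacuole_fraction < 0 || vacuole_fraction > 0.5 ||
      fibrosis_fraction < 0 || fibrosis_fraction > 0.5)
    hep_stop("config", "area fractions must lie in [0, 0.5]")
  with_seed(substream_seed(seed, "slide"), {
    h <- as.integer(height); w <- as.integer(width)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    ry <- 0.46 * h; rx <- 0.46 * w
    dy <- matrix(rep((seq_len(h) - cy) / ry, w), h, w)
    dx <- matrix(rep((seq_len(w) - cx) / rx, each = h), h, w)
    tissue <- dy^2 + dx^2 <= 1
    tissue_area <- sum(tissue)
    # interior margin so placed objects stay clear of the tissue boundary
    interior <- dy^2 + dx^2 <= 0.88
    empty <- matrix(FALSE, h, w)

    fib <- if (fibrosis_fraction > 0)
      place_ellipses(fibrosis_fraction * tissue_area, rmin = 8, rmax = 30,
                     ratio_range = c(0.6, 1), allow = interior, forbid = empty,
                     what = "fibrosis")
    else empty
    vac <- if (vacuole_fraction > 0)
      place_ellipses(vacuole_fraction * tissue_area, rmin = 5, rmax = 30,
                     ratio_range = c(0.7, 1), allow = interior, forbid = fib,
                     what = "vacuole")
    else empty

    # nuclei: small dark blobs scattered over free tissue
    nuc <- empty
    n_nuclei <- round(0.0015 * tissue_area)
    free <- which(interior & !vac & !fib, arr.ind = TRUE)
    if (n_nuclei > 0L && nrow(free) > 0L) {
      for (k in seq_len(n_nuclei)) {
        ctr <- free[sample.int(nrow(free), 1L), ]
        a <- stats::runif(1, 2, 5)
        b <- a * stats::runif(1, 0.7, 1)
        px <- ellipse_pixels(ctr[2L], ctr[1L], a, b, stats::runif(1, 0, pi),
                             h, w)
        if (is.null(px)) next
        keep <- tissue[px] & !vac[px] & !fib[px]
        px <- px[keep, , drop = FALSE]
        if (nrow(px) > 0L) nuc[px] <- TRUE
      }
    }

    col_bg <- c(0.97, 0.97, 0.97)
    col_tissue <- c(0.92, 0.72, 0.78)
    col_vac <- c(0.965, 0.955, 0.960)
    col_nuc <- c(0.38, 0.32, 0.48)
    col_fib <- c(0.32, 0.42, 0.80)
    img <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      layer <- matrix(col_bg[ch], h, w)
      layer[tissue] <- col_tissue[ch]
      layer[fib] <- col_fib[ch]
      layer[nuc] <- col_nuc[ch]
      layer[vac] <- col_vac[ch]
      img[, , ch] <- layer
    }
    img <- img + array(stats::rnorm(h * w * 3L, sd = noise_sd),
                       dim = c(h, w, 3L))
    img[img < 0] <- 0; img[img > 1] <- 1
    structure(
      list(image = img, tissue_mask = tissue, vacuole_mask = vac,
           fibrosis_mask = fib, nucleus_mask = nuc,
           vacuole_fraction = sum(vac) / tissue_area,
           fibrosis_fraction = sum(fib) / tissue_area),
      class = "synthetic_slide"
    )
  })
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_slide> %dx%d px, vacuole fraction %.3f, ",
                     "fibrosis fraction %.3f\n"),
              ncol(x$image[, , 1]), nrow(x$image[, , 1]),
              x$vacuole_fraction, x$fibrosis_fraction))
  invisible(x)
}

#' Write a cohort's inputs to disk
#'
#' Writes one expression TSV per study, a sample-metadata TSV, a comparison
#' config (YAML), the gene-set collection as GMT, and the ground truth as
#' JSON — the plain-text interchange layer of the pipeline.
#'
#' @param cohort A `synthetic_cohort` from [generate_expression_studies()].
#' @param collection Optional [gene_set_collection()] to write as GMT.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, collection = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (sid in names(cohort$studies)) {
    p <- file.path(dir, paste0(sid, "_expression.tsv"))
    write_expression(cohort$studies[[sid]], p)
    paths[paste0("expression_", sid)] <- p
  }
  meta <- do.call(rbind, lapply(cohort$comparisons, function(cs) {
    data.frame(
      sample_id = c(cs$group_a_samples, cs$group_b_samples),
      study_id = cs$study_id, comparison_id = cs$comparison_id,
      group = rep(c("A", "B"), c(length(cs$group_a_samples),
                                 length(cs$group_b_samples))),
      stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  paths["metadata"] <- write_tsv(meta, file.path(dir, "sample_metadata.tsv"))
  cfg <- list(comparisons = lapply(unname(cohort$comparisons), function(cs) {
    list(comparison_id = cs$comparison_id, study_id = cs$study_id,
         group_a_samples = cs$group_a_samples,
         group_b_samples = cs$group_b_samples,
         offspring_sex = cs$offspring_sex,
         offspring_age_weeks = cs$offspring_age_weeks,
         diet_code_a = cs$diet_code_a, diet_code_b = cs$diet_code_b)
  }))
  cfg_path <- file.path(dir, "comparisons.yaml")
  yaml::write_yaml(cfg, cfg_path)
  paths["comparisons"] <- cfg_path
  if (!is.null(collection))
    paths["gmt"] <- write_gmt(collection, file.path(dir, "gene_sets.gmt"))
  truth <- cohort$truth
  tl <- truth$true_logfc
  nz <- which(tl != 0, arr.ind = TRUE)
  truth_json <- list(
    consensus_gene_ids = truth$consensus_gene_ids,
    per_comparison_true_logfc = data.frame(
      gene = rownames(tl)[nz[, 1L]], comparison = colnames(tl)[nz[, 2L]],
      logfc = tl[nz], stringsAsFactors = FALSE),
    enriched_pathway_ids = names(truth$pathways)
  )
  tp <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth_json, tp, auto_unbox = TRUE, digits = NA)
  paths["truth"] <- tp
  invisible(paths)
}

#' Write a synthetic slide as PNG
#' @param slide A `synthetic_slide`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_slide_png <- function(slide, path) {
  png::writePNG(slide$image, path)
  invisible(path)
}
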