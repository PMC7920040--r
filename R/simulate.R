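#' Configuration for the genomic simulator
#'
#' Defines the desk-scale study conditions: two scaffolds of 2 Mb carrying
#' 500 non-overlapping genes, 20 of which form the candidate set, with SNPs
#' at 0.005 per bp (20,000 SNPs genome-wide), pools of 50 diploid
#' individuals sequenced to Poisson mean depth 100, and genome-wide
#' Balding-Nichols divergence `background_F = 0.05` (low allopatric
#' divergence). `candidate_F` applies to SNPs inside candidate gene spans;
#' it equals `background_F` by default (a null candidate set).
#'
#' @param n_scaffolds,scaffold_length genome shape.
#' @param n_genes,max_exons_per_gene,exon_length,intron_length,intergenic_gap
#'   annotation shape: exon/intron mean lengths in bp and mean intergenic
#'   gap.
#' @param snp_density SNPs per bp; `monomorphic_density` adds invariant
#'   sites at this rate.
#' @param background_F,candidate_F Balding-Nichols divergence parameters in
#'   (0, 1).
#' @param pool_size diploid individuals per pool (scalar or length 2).
#' @param mean_depth Poisson mean read depth per pool per site.
#' @param n_candidates candidate genes; `n_terms`/`term_size_range` shape
#'   the random annotation terms; `n_indels` indel positions to emit.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_scaffolds = 2L, scaffold_length = 2e6, n_genes = 500L,
                       max_exons_per_gene = 10L, exon_length = 200,
                       intron_length = 300, intergenic_gap = 4000,
                       snp_density = 0.005, monomorphic_density = 0.001,
                       background_F = 0.05, candidate_F = background_F,
                       pool_size = c(50L, 50L), mean_depth = 100,
                       n_candidates = 20L, n_terms = 40L,
                       term_size_range = c(5L, 60L), n_indels = 200L) {
  cfg <- list(n_scaffolds = as.integer(n_scaffolds),
              scaffold_length = as.numeric(scaffold_length),
              n_genes = as.integer(n_genes),
              max_exons_per_gene = as.integer(max_exons_per_gene),
              exon_length = exon_length, intron_length = intron_length,
              intergenic_gap = intergenic_gap, snp_density = snp_density,
              monomorphic_density = monomorphic_density,
              background_F = background_F, candidate_F = candidate_F,
              pool_size = rep_len(as.integer(pool_size), 2L),
              mean_depth = mean_depth, n_candidates = as.integer(n_candidates),
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              n_indels = as.integer(n_indels))
  assert_that(cfg$background_F > 0 && cfg$background_F < 1,
              "background_F must be in (0, 1)")
  assert_that(cfg$candidate_F > 0 && cfg$candidate_F < 1,
              "candidate_F must be in (0, 1)")
  assert_that(cfg$mean_depth >= 1, "mean_depth must be >= 1")
  assert_that(all(cfg$pool_size >= 1L), "pool_size must be >= 1")
  assert_that(cfg$n_candidates <= cfg$n_genes, "more candidates than genes")
  structure(cfg, class = "sim_config")
}

scaffold_names <- function(cfg) sprintf("scaf%02d", seq_len(cfg$n_scaffolds))

#' Simulate a gene annotation, candidate set and term map
#'
#' Places non-overlapping genes sequentially along each scaffold with 1 to
#' `max_exons_per_gene` exons (exon/intron/gap lengths drawn around the
#' configured means), draws `n_candidates` candidate genes uniformly, and
#' builds a term map of `n_terms` random terms plus the candidate set
#' injected as its own custom term. Deterministic under `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `genes` (gene-model table), `candidates` (gene ids),
#'   `terms` (`annotation_map`), `scaffold_lengths` (named vector).
#' @export
simulate_annotation <- function(config, seed = 1L) {
  cfg <- config
  with_seed_if(seed, {
    per <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_scaffolds + 1L)))
    scafs <- scaffold_names(cfg)
    exon_rows <- vector("list", cfg$n_scaffolds)
    gi <- 0L
    for (s in seq_len(cfg$n_scaffolds)) {
      ng <- per[s]
      if (ng == 0L) next
      n_ex <- sample.int(cfg$max_exons_per_gene, ng, replace = TRUE)
      gaps <- 1L + rpois(ng, cfg$intergenic_gap)
      tot_ex <- sum(n_ex)
      ex_len <- 50L + rpois(tot_ex, max(1, cfg$exon_length - 50))
      in_len <- 50L + rpois(tot_ex, max(1, cfg$intron_length - 50)) # last unused
      gene_idx <- rep.int(seq_len(ng), n_ex)
      # exon start offsets within each gene; span = last offset + last exon
      idx_split <- split(seq_along(gene_idx), gene_idx)
      off <- numeric(length(gene_idx))
      span <- numeric(ng)
      for (k in seq_len(ng)) {
        i <- idx_split[[k]]
        o <- cumsum(c(0, head(ex_len[i] + in_len[i], -1L)))
        off[i] <- o
        span[k] <- o[length(i)] + ex_len[i][length(i)]
      }
      gstart <- cumsum(gaps + c(0, head(span, -1L))) # 0-based gene starts
      gend <- gstart + span
      if (max(gend) > cfg$scaffold_length) {
        stop("requested genes exceed scaffold capacity on ", scafs[s],
             call. = FALSE)
      }
      exon_rows[[s]] <- tibble::tibble(
        gene_id = sprintf("gene%05d", gi + gene_idx),
        scaffold = scafs[s],
        strand = rep(sample(c("+", "-"), ng, replace = TRUE), n_ex),
        start = as.integer(gstart[gene_idx] + off),
        end = as.integer(gstart[gene_idx] + off + ex_len))
      gi <- gi + ng
    }
    genes <- dplyr::bind_rows(exon_rows)
    genes <- gene_models(genes$gene_id, genes$scaffold, genes$strand,
                         genes$start, genes$end)
    ids <- unique(genes$gene_id)
    candidates <- sort(sample(ids, cfg$n_candidates))
    sizes <- sample(seq(cfg$term_size_range[1L], cfg$term_size_range[2L]),
                    cfg$n_terms, replace = TRUE)
    terms <- lapply(sizes, function(k) sample(ids, min(k, length(ids))))
    names(terms) <- sprintf("TERM:%04d", seq_len(cfg$n_terms))
    map <- annotation_map(terms)
    map <- add_candidate_term(map, candidates, "custom:phagocytosis",
                              "phagocytosis candidate gene set")
    list(genes = genes, candidates = candidates, terms = map,
         scaffold_lengths = setNames(rep(cfg$scaffold_length, cfg$n_scaffolds),
                                     scafs))
  })
}

#' Simulate two-pool divergence data under the Balding-Nichols model
#'
#' Per SNP: ancestral frequency `p ~ U(0.05, 0.95)`; each population's
#' frequency `q_i ~ Beta(p (1-F)/F, (1-p)(1-F)/F)` so that the expected
#' fixation index equals `F`; the pool's sampled allele frequency is
#' `Binomial(2 pool_size, q_i) / (2 pool_size)` (individual sampling); read
#' depth is `Poisson(mean_depth)` per pool and alternate-allele reads are
#' `Binomial(depth, pool frequency)` (read sampling). SNPs inside candidate
#' gene spans use `candidate_F`, all others `background_F`. Invariant
#' (monomorphic) sites are added at `monomorphic_density`. Reference and
#' alternate alleles are drawn among A/C/G/T.
#'
#' @param config a [sim_config()].
#' @param annotation optional [simulate_annotation()] result; needed when
#'   `candidate_F` differs from `background_F`.
#' @param seed integer seed.
#' @return list with `sites` (sync tibble of SNP + invariant sites, sorted
#'   by scaffold and position) and `truth` (tibble per SNP: `scaffold`,
#'   `position`, `ref`, `alt`, `F`, `p_anc`, `q1`, `q2`, `x1`, `x2`,
#'   `depth1`, `depth2`, `in_candidate`).
#' @export
simulate_divergence <- function(config, annotation = NULL, seed = 1L) {
  cfg <- config
  bases <- c("A", "C", "G", "T")
  with_seed_if(seed, {
    scafs <- scaffold_names(cfg)
    L <- cfg$scaffold_length
    n_snp <- round(L * cfg$snp_density)
    n_mono <- round(L * cfg$monomorphic_density)
    per_scaf <- lapply(scafs, function(sc) {
      pos <- sort(sample.int(L, n_snp + n_mono))
      is_snp <- sample(rep(c(TRUE, FALSE), c(n_snp, n_mono)))
      tibble::tibble(scaffold = sc, position = pos, is_snp = is_snp)
    })
    sites <- dplyr::bind_rows(per_scaf)
    n <- nrow(sites)

    in_cand <- rep(FALSE, n)
    if (!is.null(annotation)) {
      sp <- gene_spans(annotation$genes)
      cand_sp <- sp[sp$gene_id %in% annotation$candidates, , drop = FALSE]
      in_cand <- positions_in_intervals(sites$scaffold, sites$position,
                                        cand_sp[c("scaffold", "start", "end")])
    }
    Fv <- ifelse(in_cand, cfg$candidate_F, cfg$background_F)

    ref_i <- sample.int(4L, n, replace = TRUE)
    alt_i <- 1L + (ref_i - 1L + sample.int(3L, n, replace = TRUE)) %% 4L

    snp <- sites$is_snp
    ns <- sum(snp)
    p_anc <- runif(ns, 0.05, 0.95)
    a <- p_anc * (1 - Fv[snp]) / Fv[snp]
    b <- (1 - p_anc) * (1 - Fv[snp]) / Fv[snp]
    q1 <- rbeta(ns, a, b)
    q2 <- rbeta(ns, a, b)
    x1 <- rbinom(ns, 2L * cfg$pool_size[1L], q1) / (2 * cfg$pool_size[1L])
    x2 <- rbinom(ns, 2L * cfg$pool_size[2L], q2) / (2 * cfg$pool_size[2L])
    d1 <- rpois(n, cfg$mean_depth)
    d2 <- rpois(n, cfg$mean_depth)
    alt1 <- integer(n); alt2 <- integer(n)
    alt1[snp] <- rbinom(ns, d1[snp], x1)
    alt2[snp] <- rbinom(ns, d2[snp], x2)

    cnt1 <- matrix(0L, n, 6L); cnt2 <- matrix(0L, n, 6L)
    # sync column order A,T,C,G,N,del; allele bases are A,C,G,T
    col_of <- c(A = 1L, C = 3L, G = 4L, T = 2L)
    rc <- col_of[bases[ref_i]]; ac <- col_of[bases[alt_i]]
    cnt1[cbind(seq_len(n), rc)] <- d1 - alt1
    cnt1[cbind(seq_len(n), ac)] <- cnt1[cbind(seq_len(n), ac)] + alt1
    cnt2[cbind(seq_len(n), rc)] <- d2 - alt2
    cnt2[cbind(seq_len(n), ac)] <- cnt2[cbind(seq_len(n), ac)] + alt2

    sync <- sync_sites(sites$scaffold, sites$position, bases[ref_i], cnt1, cnt2)
    truth <- tibble::tibble(
      scaffold = sites$scaffold[snp], position = sites$position[snp],
      ref = bases[ref_i[snp]], alt = bases[alt_i[snp]],
      F = Fv[snp], p_anc = p_anc, q1 = q1, q2 = q2, x1 = x1, x2 = x2,
      depth1 = d1[snp], depth2 = d2[snp], in_candidate = in_cand[snp])
    list(sites = sync, truth = truth)
  })
}

#' Simulate indel positions
#'
#' Uniform positions per scaffold, emitted in the two-column TSV layout the
#' masking stage consumes. Indels are pure nuisance here: they exist so the
#' indel-window masking step has realistic input.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return tibble with `scaffold`, `position`.
#' @export
simulate_indels <- function(config, seed = 1L) {
  cfg <- config
  with_seed_if(seed, {
    per <- diff(round(seq(0, cfg$n_indels, length.out = cfg$n_scaffolds + 1L)))
    dplyr::bind_rows(lapply(seq_len(cfg$n_scaffolds), function(s) {
      tibble::tibble(scaffold = scaffold_names(cfg)[s],
                     position = sort(sample.int(cfg$scaffold_length, per[s])))
    }))
  })
}

#' Configuration for the immune-assay cohort simulator
#'
#' Mirrors the larval assay design: `n_per_group` individuals per
#' population x sex cell, two replicate slides each contributing around
#' `cells_per_replicate` scored hemocytes, total hemocyte concentration
#' negative-binomial with mean 14,037 and SD 7,125 cells/uL (the scale of
#' fifth-instar larval counts), cell-type composition
#' Dirichlet-multinomial with granulocytes dominant, and per-type
#' phagocytosis propensities on the logit scale: a population base (0.80
#' north vs 0.67 south, echoing the reported group contrast), a positive
#' male effect, and type offsets.
#'
#' @param n_per_group individuals per population x sex group (default 11).
#' @param populations,sexes group labels.
#' @param n_replicates slides per individual.
#' @param cells_per_replicate Poisson mean of scored cells per slide.
#' @param thc_mean,thc_sd total-hemocyte-count distribution (cells/uL).
#' @param n_squares,dilution_fraction hemocytometer protocol.
#' @param composition mean cell-type proportions;
#'   `dirichlet_concentration` controls between-individual variation.
#' @param propensity_population per-population base propensity.
#' @param sex_logit_effect additive logit effect for males.
#' @param type_logit_effect additive logit offsets per cell type.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 11L,
                          populations = c("north", "south"),
                          sexes = c("F", "M"), n_replicates = 2L,
                          cells_per_replicate = 100,
                          thc_mean = 14037, thc_sd = 7125,
                          n_squares = 10L, dilution_fraction = 1 / 20,
                          composition = c(granulocyte = 0.55,
                                          plasmatocyte = 0.30,
                                          oenocytoid = 0.10, other = 0.05),
                          dirichlet_concentration = 60,
                          propensity_population = c(north = 0.80, south = 0.67),
                          sex_logit_effect = 0.25,
                          type_logit_effect = c(granulocyte = 0.35,
                                                plasmatocyte = 0,
                                                oenocytoid = -0.35,
                                                other = -1.2)) {
  cfg <- list(n_per_group = as.integer(n_per_group), populations = populations,
              sexes = sexes, n_replicates = as.integer(n_replicates),
              cells_per_replicate = cells_per_replicate, thc_mean = thc_mean,
              thc_sd = thc_sd, n_squares = as.integer(n_squares),
              dilution_fraction = dilution_fraction, composition = composition,
              dirichlet_concentration = dirichlet_concentration,
              propensity_population = propensity_population,
              sex_logit_effect = sex_logit_effect,
              type_logit_effect = type_logit_effect)
  assert_that(abs(sum(cfg$composition) - 1) < 1e-8, "composition must sum to 1")
  assert_that(all(cfg$propensity_population >= 0 & cfg$propensity_population <= 1),
              "propensities must be in [0, 1]")
  assert_that(all(names(cfg$propensity_population) == cfg$populations),
              "propensity_population must be named by population")
  assert_that(cfg$thc_sd^2 > cfg$thc_mean,
              "thc_sd^2 must exceed thc_mean (negative-binomial overdispersion)")
  structure(cfg, class = "cohort_config")
}

# the generating propensity for each population x sex x type cell
cohort_truth_propensities <- function(cfg) {
  g <- expand.grid(population = cfg$populations, sex = cfg$sexes,
                   cell_type = names(cfg$composition),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$propensity <- plogis(
    qlogis(cfg$propensity_population[g$population]) +
      cfg$sex_logit_effect * (g$sex == "M") +
      cfg$type_logit_effect[g$cell_type])
  tibble::as_tibble(g)
}

#' Simulate an immune-assay cohort with known ground truth
#'
#' Per larva: a true hemocyte concentration (negative binomial), a
#' hemocytometer observation (Poisson around the chamber expectation), an
#' individual cell-type composition (Dirichlet around the cohort means),
#' and per replicate slide a multinomial split of the scored cells with
#' binomial phagocytosis per type at the group's generating propensity.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return list with `counts` (tidy cell-count tibble consumable by
#'   [phagocytic_index()] and friends), `hemocytometer` (per-larva counts
#'   with `thc_true`), and `truth` (list: `propensities` tibble,
#'   `composition`, `thc_mean`, `thc_sd`).
#' @export
simulate_cohort <- function(config, seed = 1L) {
  cfg <- config
  types <- names(cfg$composition)
  prop <- cohort_truth_propensities(cfg)
  with_seed_if(seed, {
    grid <- expand.grid(sex = cfg$sexes, population = cfg$populations,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- list(); hemo <- list(); id <- 0L
    for (g in seq_len(nrow(grid))) {
      popn <- grid$population[g]; sx <- grid$sex[g]
      pr <- setNames(prop$propensity[prop$population == popn & prop$sex == sx],
                     prop$cell_type[prop$population == popn & prop$sex == sx])
      for (ind in seq_len(cfg$n_per_group)) {
        id <- id + 1L
        iid <- sprintf("larva%03d", id)
        thc <- rnbinom(1L, mu = cfg$thc_mean,
                       size = cfg$thc_mean^2 / (cfg$thc_sd^2 - cfg$thc_mean))
        cells_seen <- rpois(1L, thc * cfg$n_squares * cfg$dilution_fraction / 10)
        hemo[[id]] <- tibble::tibble(individual_id = iid, population = popn,
                                     sex = sx, cells_counted = cells_seen,
                                     n_squares = cfg$n_squares,
                                     dilution_fraction = cfg$dilution_fraction,
                                     thc_true = thc)
        alpha <- cfg$composition * cfg$dirichlet_concentration
        w <- rgamma(length(types), shape = alpha)
        pcomp <- w / sum(w)
        for (rep_i in seq_len(cfg$n_replicates)) {
          ncells <- rpois(1L, cfg$cells_per_replicate)
          tot <- as.integer(stats::rmultinom(1L, ncells, pcomp))
          phag <- rbinom(length(types), tot, pr[types])
          rows[[length(rows) + 1L]] <- tibble::tibble(
            individual_id = iid, population = popn, sex = sx,
            replicate_id = paste0("slide", rep_i), cell_type = types,
            n_total = tot, n_phagocytic = as.integer(phag))
        }
      }
    }
    list(counts = validate_cell_counts(dplyr::bind_rows(rows)),
         hemocytometer = dplyr::bind_rows(hemo),
         truth = list(propensities = prop, composition = cfg$composition,
                      thc_mean = cfg$thc_mean, thc_sd = cfg$thc_sd))
  })
}

#' Write a cell-count table as CSV
#' @param counts tidy cell-count tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_counts <- function(counts, path) {
  write.csv(counts, path, row.names = FALSE)
  invisible(path)
}
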