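#' Simulation configuration
#'
#' Bundles the parameters of all synthetic-data generators. The defaults
#' mirror the study design the analysis modules target: two ChIP-seq peak
#' replicates with overlap fractions straddling the 0.5 consensus cut-off and
#' FDR/tag-density marginals straddling the FDR < 10 / TD > 15 gate;
#' summit-centred Gaussian tag enrichment over a uniform Poisson background;
#' and a NanoString-style log-normal count matrix with 24 normal / 58 tumour
#' samples, a FOXM1 anchor elevated in tumours, a planted block of
#' anchor-correlated genes, anti-correlated genes, five near-constant
#' reference genes and a geometric positive-control ladder.
#'
#' @param seed integer seed; every generator is a pure function of its config.
#' @param genome named vector of chromosome lengths (bp).
#' @param n_pairs number of rep1/rep2 peak pairs to plant.
#' @param n_unique_per_set extra unmatched peaks per replicate.
#' @param peak_length_range min/max peak length (bp).
#' @param overlap_fracs vector of overlap fractions the planted pairs cycle
#'   through (values straddling 0.5 by default).
#' @param gate_pass_prob probability that a planted peak passes the FDR/TD
#'   gate.
#' @param tag_background_rate background tag rate (tags per bp).
#' @param tags_per_peak expected enriched tags per peak.
#' @param tag_sd standard deviation (bp) of the Gaussian enrichment around
#'   the summit.
#' @param n_normal,n_tumour sample sizes for the expression matrix.
#' @param anchor_log2_effect tumour-vs-normal log2 effect on the anchor gene.
#' @param n_corr,corr_r size and true latent Pearson correlation of the
#'   anchor-correlated gene block.
#' @param n_anti,anti_r size and (negative) correlation of the
#'   anti-correlated block.
#' @param n_null number of unrelated endogenous genes.
#' @param noise_sd log-scale residual noise sd for endogenous genes.
#' @param block_sd log2 sd of the correlated/anti-correlated gene blocks.
#' @param lane_sd log2 sd of the per-sample lane factor that normalisation
#'   must remove (0 disables it).
#' @param kd_noise_sd log2 replicate noise in the knockdown simulation.
#' @param ref_cv coefficient of variation of the reference genes.
#' @param base_log2_mean log2 baseline count level of endogenous genes.
#' @param kd_replicates replicates per knockdown arm.
#' @param kd_log2_effects named list: per-arm named vectors of per-gene log2
#'   effects (defaults plant FOXM1- and LIN9-responsive genes with one
#'   discordant gene).
#' @return a list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1,
                       genome = c(chr1 = 5e6, chr2 = 5e6),
                       n_pairs = 30,
                       n_unique_per_set = 10,
                       peak_length_range = c(200, 800),
                       overlap_fracs = c(0.2, 0.4, 0.49, 0.5, 0.6, 0.8, 1),
                       gate_pass_prob = 0.7,
                       tag_background_rate = 0.001,
                       tags_per_peak = 200,
                       tag_sd = 100,
                       n_normal = 24,
                       n_tumour = 58,
                       anchor_log2_effect = 2,
                       n_corr = 20, corr_r = 0.8,
                       n_anti = 5, anti_r = -0.6,
                       n_null = 20,
                       noise_sd = 0.5,
                       block_sd = 0.5,
                       lane_sd = 0.25,
                       kd_noise_sd = 0.15,
                       ref_cv = 0.05,
                       base_log2_mean = 9,
                       kd_replicates = 3,
                       kd_log2_effects = NULL) {
  if (seed != as.integer(seed)) stop("seed must be an integer")
  stopifnot(all(genome > 0), n_pairs >= 0, n_unique_per_set >= 0,
            all(peak_length_range > 0), gate_pass_prob >= 0,
            gate_pass_prob <= 1, tag_background_rate >= 0,
            tags_per_peak >= 0, tag_sd > 0, n_normal >= 0, n_tumour >= 1,
            abs(corr_r) <= 1, abs(anti_r) <= 1, noise_sd >= 0, ref_cv >= 0,
            kd_replicates >= 2)
  if (is.null(kd_log2_effects)) {
    kd_log2_effects <- list(
      siFOXM1 = c(FOXM1 = -2, CCNB1 = -1.5, UBE2C = -1.2, CENPF = -1,
                  UHRF1 = -1, NDE1 = -0.8, ARHGAP19 = -0.9),
      siLIN9 = c(LIN9 = -2, CCNB1 = -1.2, UBE2C = -1, HMGB3 = -1.5,
                 UHRF1 = -0.7, ARHGAP19 = 0.9))
  }
  structure(as.list(environment()), class = "SimulationConfig")
}

# independent RNG stream per generator so generators are pure in (cfg, name)
with_sim_seed <- function(cfg, stream, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed + stream, kind = "Mersenne-Twister")
  force(code)
}

#' Simulate two ChIP-seq peak replicates with known consensus truth
#'
#' Plants `n_pairs` rep1/rep2 peak pairs at well-separated positions with
#' controlled smaller-peak overlap fractions and known FDR/tag-density gate
#' outcomes, plus unmatched peaks in each replicate. The returned truth table
#' records, per pair, the overlap fraction and whether the pair must survive
#' [replicate_consensus()] at its default thresholds.
#'
#' @param cfg a [sim_config()].
#' @return list with `rep1`, `rep2` ([peak_set()]s) and `truth` (data frame
#'   with `pair`, `rep1_id`, `rep2_id`, `overlap_frac`, `gate1`, `gate2`,
#'   `survives`).
#' @export
simulate_peak_replicates <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_sim_seed(cfg, 101L, {
    n <- cfg$n_pairs
    chroms <- names(cfg$genome)
    spacing <- 20000
    total_slots <- n + 2 * cfg$n_unique_per_set
    per_chr <- floor((cfg$genome - 2 * spacing) / spacing)
    if (sum(per_chr) < total_slots)
      stop("infeasible plan: genome too small for requested peaks")
    slot_chr <- rep(chroms, per_chr)[seq_len(total_slots)]
    slot_pos <- unlist(lapply(chroms, function(c)
      seq(spacing, by = spacing, length.out = per_chr[[c]])))[seq_len(total_slots)]
    perm <- sample.int(total_slots)
    slot_chr <- slot_chr[perm]; slot_pos <- slot_pos[perm]

    fr <- rep_len(cfg$overlap_fracs, max(n, 1))[seq_len(n)]
    len1 <- round(stats::runif(n, cfg$peak_length_range[1],
                               cfg$peak_length_range[2]))
    len2 <- round(stats::runif(n, cfg$peak_length_range[1],
                               cfg$peak_length_range[2]))
    draw_gate <- function(pass) {
      # pass: fdr < 10 and td > 15 (strict); fail: violate at least one
      fdr <- ifelse(pass, stats::runif(n, 0, 9.5),
                    ifelse(stats::runif(n) < 0.5,
                           stats::runif(n, 10, 40),
                           stats::runif(n, 0, 9.5)))
      td <- ifelse(pass, stats::runif(n, 16, 60), stats::runif(n, 1, 15))
      # fdr-failing draws may still have high td; td-failing draws keep any fdr
      list(fdr = fdr, td = td)
    }
    pass1 <- stats::runif(n) < cfg$gate_pass_prob
    pass2 <- stats::runif(n) < cfg$gate_pass_prob
    g1 <- draw_gate(pass1); g2 <- draw_gate(pass2)
    # ensure "fail" really fails the (fdr < 10 AND td > 15) conjunction
    g1$td[!pass1] <- pmin(g1$td[!pass1], 15)
    g2$td[!pass2] <- pmin(g2$td[!pass2], 15)

    s1 <- slot_pos[seq_len(n)]
    e1 <- s1 + len1
    # overlap = fr * min(len1, len2): shift rep2 so the intersection is exact
    ov <- round(fr * pmin(len1, len2))
    s2 <- e1 - ov
    e2 <- s2 + len2
    chr12 <- slot_chr[seq_len(n)]

    u_idx <- n + seq_len(2 * cfg$n_unique_per_set)
    u_chr <- slot_chr[u_idx]; u_pos <- slot_pos[u_idx]
    u_len <- round(stats::runif(length(u_idx), cfg$peak_length_range[1],
                                cfg$peak_length_range[2]))
    half <- seq_len(cfg$n_unique_per_set)

    mk_set <- function(chrom, start, end, fdr, td, label) {
      summit <- floor((start + end) / 2)
      peak_set(chrom, start, end, summit, fdr, td, label = label)
    }
    rep1 <- mk_set(c(chr12, u_chr[half]),
                   c(s1, u_pos[half]), c(e1, u_pos[half] + u_len[half]),
                   c(g1$fdr, stats::runif(cfg$n_unique_per_set, 0, 40)),
                   c(g1$td, stats::runif(cfg$n_unique_per_set, 1, 60)),
                   "rep1")
    rep2 <- mk_set(c(chr12, u_chr[-half]),
                   c(s2, u_pos[-half]), c(e2, u_pos[-half] + u_len[-half]),
                   c(g2$fdr, stats::runif(cfg$n_unique_per_set, 0, 40)),
                   c(g2$td, stats::runif(cfg$n_unique_per_set, 1, 60)),
                   "rep2")
    # recover planted ids after peak_set's coordinate sort
    id1 <- rep1$peak_id[match(paste(chr12, s1), paste(rep1$chrom, rep1$start))]
    id2 <- rep2$peak_id[match(paste(chr12, s2), paste(rep2$chrom, rep2$start))]
    actual_fr <- ov / pmin(len1, len2)
    truth <- data.frame(pair = seq_len(n), rep1_id = id1, rep2_id = id2,
                        overlap_frac = actual_fr,
                        gate1 = pass1, gate2 = pass2,
                        survives = actual_fr >= 0.5 & (pass1 | pass2),
                        stringsAsFactors = FALSE)
    list(rep1 = rep1, rep2 = rep2, truth = truth)
  })
}

#' Simulate single-base tag positions around peak summits
#'
#' Draws a uniform Poisson background over the genome plus, for each peak,
#' `Poisson(tags_per_peak)` enriched tags at positions
#' `round(N(summit, tag_sd))`, truncated to the chromosome.
#'
#' @param cfg a [sim_config()].
#' @param peaks a [peak_set()].
#' @return data frame `chrom`, `pos`, `count` (one row per tag, count 1),
#'   sorted by position.
#' @export
simulate_tags <- function(cfg, peaks) {
  stopifnot(inherits(cfg, "SimulationConfig"), inherits(peaks, "PeakSet"))
  with_sim_seed(cfg, 202L, {
    bg <- lapply(names(cfg$genome), function(c) {
      nb <- stats::rpois(1, cfg$tag_background_rate * cfg$genome[[c]])
      if (!nb) return(NULL)
      data.frame(chrom = c, pos = floor(stats::runif(nb, 0, cfg$genome[[c]])))
    })
    en <- lapply(seq_len(nrow(peaks)), function(i) {
      ne <- stats::rpois(1, cfg$tags_per_peak)
      if (!ne) return(NULL)
      p <- round(stats::rnorm(ne, peaks$summit[i], cfg$tag_sd))
      p <- pmin(pmax(p, 0), cfg$genome[[peaks$chrom[i]]] - 1)
      data.frame(chrom = peaks$chrom[i], pos = p)
    })
    out <- do.call(rbind, c(bg, en))
    if (is.null(out))
      return(data.frame(chrom = character(), pos = numeric(),
                        count = numeric()))
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out$count <- 1
    out
  })
}

#' Simulate a NanoString-style expression count matrix with ground truth
#'
#' Endogenous genes are generated on a latent log2 scale: the anchor gene
#' (`FOXM1`) gets a tumour-vs-normal shift of `anchor_log2_effect`; a block of
#' `n_corr` genes is built from the anchor's standardised latent signal so
#' its true latent Pearson correlation with the anchor is `corr_r`
#' (`anti_r` for the anti-correlated block); `n_null` genes are independent
#' noise. Five reference genes (`SDHA`, `ALAS1`, `GAPDH`, `HMBS`, `PARPBP`)
#' are constant up to `ref_cv`, and six positive-control probes form a
#' four-fold geometric ladder. A per-sample lane factor multiplies all probes
#' (what normalisation must remove). Counts are `round(2^latent)`.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (a [count_matrix()] whose `sample_meta` has
#'   `group` = normal/tumour and `t_stage` = early/late for tumours) and
#'   `truth` (per-gene data frame with `planted_r`, `tumour_log2_effect`).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (cfg$n_normal > 0 && cfg$n_normal < 2) stop("n_normal must be 0 or >= 2")
  with_sim_seed(cfg, 303L, {
    ns <- cfg$n_normal + cfg$n_tumour
    sample_id <- c(sprintf("NRML_%02d", seq_len(cfg$n_normal)),
                   sprintf("OAC_%02d", seq_len(cfg$n_tumour)))
    tumour <- rep(c(FALSE, TRUE), c(cfg$n_normal, cfg$n_tumour))

    corr_genes <- sprintf("TGT%02d", seq_len(cfg$n_corr))
    anti_genes <- if (cfg$n_anti) sprintf("ANTI%02d", seq_len(cfg$n_anti))
                  else character()
    null_genes <- if (cfg$n_null) sprintf("NULL%02d", seq_len(cfg$n_null))
                  else character()
    endo <- c("FOXM1", corr_genes, anti_genes, null_genes)

    anchor <- cfg$base_log2_mean + cfg$anchor_log2_effect * tumour +
      stats::rnorm(ns, 0, cfg$noise_sd)
    za <- as.numeric(scale(anchor))
    lat <- matrix(0, length(endo), ns, dimnames = list(endo, sample_id))
    lat["FOXM1", ] <- anchor
    mk_block <- function(genes, r) {
      for (g in genes)
        lat[g, ] <<- cfg$base_log2_mean +
          cfg$block_sd * (r * za + sqrt(1 - r^2) * stats::rnorm(ns))
    }
    mk_block(corr_genes, cfg$corr_r)
    mk_block(anti_genes, cfg$anti_r)
    for (g in null_genes)
      lat[g, ] <- cfg$base_log2_mean + stats::rnorm(ns, 0, cfg$noise_sd)

    refs <- c("SDHA", "ALAS1", "GAPDH", "HMBS", "PARPBP")
    ref_lat <- matrix(cfg$base_log2_mean +
                        stats::rnorm(length(refs) * ns, 0,
                                     log2(1 + cfg$ref_cv)),
                      length(refs), ns, dimnames = list(refs, sample_id))
    pos <- sprintf("POS_%s", LETTERS[1:6])
    ladder <- cfg$base_log2_mean + 3 - 2 * (0:5)  # four-fold steps
    pos_lat <- matrix(rep(ladder, ns), length(pos), ns,
                      dimnames = list(pos, sample_id))

    lane <- stats::rnorm(ns, 0, cfg$lane_sd)  # per-sample log2 lane factor
    all_lat <- sweep(rbind(lat, ref_lat, pos_lat), 2, lane, `+`)
    counts <- round(2^all_lat)

    meta <- data.frame(sample_id = sample_id,
                       group = ifelse(tumour, "OAC", "normal"),
                       t_stage = ifelse(tumour,
                                        sample(c("early", "late"),
                                               ns, replace = TRUE),
                                        NA_character_),
                       stringsAsFactors = FALSE)
    cm <- count_matrix(counts,
                       c(rep("endogenous", length(endo)),
                         rep("reference", length(refs)),
                         rep("positive_control", length(pos))),
                       meta)
    truth <- data.frame(gene_id = endo,
                        planted_r = c(1, rep(cfg$corr_r, cfg$n_corr),
                                      rep(cfg$anti_r, cfg$n_anti),
                                      rep(0, cfg$n_null)),
                        tumour_log2_effect = c(cfg$anchor_log2_effect,
                                               rep(0, length(endo) - 1)),
                        stringsAsFactors = FALSE)
    list(counts = cm, truth = truth)
  })
}

#' Simulate a replicated siRNA knockdown experiment
#'
#' Control (`siNTC`) plus one arm per entry of `cfg$kd_log2_effects`, each
#' with `kd_replicates` replicates. Per-gene log2 effects are applied to the
#' treated arms on top of shared baselines and log-normal noise.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (a [count_matrix()]; `sample_meta$condition`
#'   holds the arm) and `truth` (data frame `gene_id`, `arm`, `log2_effect`).
#' @export
simulate_knockdown <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_sim_seed(cfg, 404L, {
    arms <- c("siNTC", names(cfg$kd_log2_effects))
    genes <- sort(unique(c(unlist(lapply(cfg$kd_log2_effects, names)),
                           "FOXM1", "LIN9", "CCNB1", "UBE2C", "PLK1",
                           "CENPF", "UHRF1", "HMGB3", "NDE1", "ARHGAP19",
                           "CDKN3", "NULL01", "NULL02", "NULL03")))
    refs <- c("ALAS1", "GAPDH", "HMBS")
    r <- cfg$kd_replicates
    sample_id <- unlist(lapply(arms, function(a) sprintf("%s_r%d", a, 1:r)))
    cond <- rep(arms, each = r)
    base <- stats::setNames(stats::runif(length(genes), 8, 11), genes)
    lat <- matrix(rep(base, length(sample_id)), length(genes),
                  dimnames = list(genes, sample_id))
    for (a in names(cfg$kd_log2_effects)) {
      eff <- cfg$kd_log2_effects[[a]]
      lat[names(eff), cond == a] <- lat[names(eff), cond == a] + eff
    }
    lat <- lat + stats::rnorm(length(lat), 0, cfg$kd_noise_sd)
    ref_lat <- matrix(cfg$base_log2_mean +
                        stats::rnorm(length(refs) * length(sample_id), 0,
                                     log2(1 + cfg$ref_cv)),
                      length(refs), dimnames = list(refs, sample_id))
    pos <- sprintf("POS_%s", LETTERS[1:6])
    pos_lat <- matrix(rep(cfg$base_log2_mean + 3 - 2 * (0:5),
                          length(sample_id)),
                      length(pos), dimnames = list(pos, sample_id))
    counts <- round(2^rbind(lat, ref_lat, pos_lat))
    meta <- data.frame(sample_id = sample_id, condition = cond,
                       stringsAsFactors = FALSE)
    cm <- count_matrix(counts,
                       c(rep("endogenous", length(genes)),
                         rep("reference", length(refs)),
                         rep("positive_control", length(pos))),
                       meta)
    truth <- do.call(rbind, lapply(names(cfg$kd_log2_effects), function(a)
      data.frame(gene_id = names(cfg$kd_log2_effects[[a]]), arm = a,
                 log2_effect = unname(cfg$kd_log2_effects[[a]]),
                 stringsAsFactors = FALSE)))
    list(counts = cm, truth = truth)
  })
}
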