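# Seeded simulator of a miniature innate-immune activation study: 6 donors
# x 5 conditions (UT, LPS2, LPS6/6, LPS24, IFNG), two ATAC replicates and
# one RNA library per donor/condition, NB-distributed counts with planted
# condition effects, distal peaks carrying correlated eRNA signal,
# centre-peaked conservation, and context-specific eQTLs grouped in
# credible sets. The layout places one gene and at most a few peaks per
# fixed-size "slot" so that proximal (<= 3 kb) and distal (> 3 kb) peak
# placement, and eRNA windows clear of padded gene boundaries, are all
# guaranteed by construction. Truth tables record every planted effect for
# parameter-recovery testing.

#' Simulation specification
#'
#' All knobs of the synthetic study, with defaults matching the study
#' design being emulated (sample sizes) or chosen once for desk-scale power
#' (effect sizes; see the package vignette).
#'
#' @param n_donors number of donors (6).
#' @param n_atac_replicates ATAC replicates per donor/condition (2; RNA has
#'   one library each).
#' @param n_genes,n_peaks number of genes and ATAC peaks (2000 each).
#' @param frac_differential fraction of peaks (and, via inheritance plus
#'   top-up, genes) with a planted condition effect (0.2, the order
#'   observed for differential ATAC peaks in stimulated monocytes).
#' @param planted_lfc mean absolute planted log2 fold change (2).
#' @param lfc_sd per-feature spread of the planted magnitude (0.5).
#' @param nb_dispersion NB dispersion alpha, variance = mu + alpha mu^2
#'   (0.1).
#' @param mean_count_log_range log10 range of baseline means (10..1000).
#' @param donor_sd sd of per-feature, per-donor log-normal factors (0.15).
#' @param depth_sd sd of per-sample log-normal depth factors (0.2).
#' @param frac_distal fraction of non-differential peaks placed > 3 kb from
#'   any TSS (0.46, the proportion observed for non-differential peaks).
#' @param frac_distal_differential distal fraction among differential peaks
#'   (0.64, the observed distal skew of stimulation-responsive regions).
#' @param frac_erna_active fraction of distal peaks with eRNA signal (0.5).
#' @param erna_atac_r target Pearson correlation between planted eRNA and
#'   ATAC log2 fold changes (0.6).
#' @param frac_context_eqtl probability that a differential peak's lead
#'   eQTL condition matches its planted condition (0.8).
#' @param frac_eqtl_peaks fraction of detectable peaks carrying an eQTL
#'   credible set (0.5).
#' @param call_prob_high,call_prob_low,frac_low_detect per-sample peak-call
#'   probability for well-detected peaks (0.9) and for the
#'   `frac_low_detect` (0.15) poorly detected ones (0.15), so the >= 30
#'   percent recurrence filter sees both retained and dropped peaks.
#' @param frac_weak_call fraction of calls given sub-threshold significance
#'   (-log10 p < 5) (0.05).
#' @param frac_blacklist fraction of peaks covered by a blacklist interval
#'   (0.02).
#' @param amp_diff,amp_nondiff conservation bump amplitude at differential
#'   (0.75) and non-differential (1.5) peak midpoints.
#' @param cons_noise_sd,cons_bump_sd conservation baseline noise sd (0.3)
#'   and Gaussian bump sd in bp (300).
#' @param peak_width,gene_length,slot_bp,n_contigs genome layout (400 bp
#'   peaks, 2 kb genes, 20 kb slots, 4 contigs).
#' @param seed integer RNG seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_donors = 6, n_atac_replicates = 2,
                            n_genes = 2000, n_peaks = 2000,
                            frac_differential = 0.2, planted_lfc = 2,
                            lfc_sd = 0.5, nb_dispersion = 0.1,
                            mean_count_log_range = c(1, 3),
                            donor_sd = 0.15, depth_sd = 0.2,
                            frac_distal = 0.46, frac_distal_differential = 0.64,
                            frac_erna_active = 0.5,
                            erna_atac_r = 0.6, frac_context_eqtl = 0.8,
                            frac_eqtl_peaks = 0.5,
                            call_prob_high = 0.9, call_prob_low = 0.15,
                            frac_low_detect = 0.15, frac_weak_call = 0.05,
                            frac_blacklist = 0.02,
                            amp_diff = 0.75, amp_nondiff = 1.5,
                            cons_noise_sd = 0.3, cons_bump_sd = 300,
                            peak_width = 400, gene_length = 2000,
                            slot_bp = 20000, n_contigs = 4, seed = 1) {
  spec <- as.list(environment())
  fracs <- c("frac_differential", "frac_distal", "frac_distal_differential",
             "frac_erna_active",
             "frac_context_eqtl", "frac_eqtl_peaks", "frac_low_detect",
             "frac_weak_call", "frac_blacklist",
             "call_prob_high", "call_prob_low")
  if (any(unlist(spec[fracs]) < 0 | unlist(spec[fracs]) > 1)) {
    stop("fractions and probabilities must lie in [0, 1]")
  }
  if (spec$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (spec$n_peaks <= 0) stop("n_peaks must be positive")
  if (spec$n_genes < 0) stop("n_genes must be >= 0")
  if (spec$gene_length > 4000 || spec$slot_bp < 20000) {
    stop("slot too small: need gene_length <= 4000 and slot_bp >= 20000")
  }
  structure(spec, class = "simulation_spec")
}

# slot layout: slot i (1-based) spans [slot_start, slot_start + slot_bp);
# gene at offset 4000; distal midpoints drawn from [10000, 18000) within
# the slot, which keeps them > 3 kb from every TSS and their +-1 kb eRNA
# window clear of every padded (+-3 kb) gene boundary.
slot_layout <- function(spec) {
  n_slots <- max(spec$n_genes, spec$n_peaks)
  per_contig <- ceiling(n_slots / spec$n_contigs)
  contig <- paste0("chr", (seq_len(n_slots) - 1) %/% per_contig + 1)
  within <- (seq_len(n_slots) - 1) %% per_contig
  start <- within * spec$slot_bp
  lens <- tapply(start + spec$slot_bp, contig, max)
  list(n_slots = n_slots, contig = contig, start = start,
       contig_lengths = setNames(as.integer(lens) + spec$slot_bp, names(lens)))
}

#' Generate the synthetic gene annotation
#'
#' Non-overlapping genes of fixed length, alternating strand, one per slot
#' on a small set of contigs.
#'
#' @param spec a [simulation_spec()].
#' @return list: `genes` (annotation data.frame), `contig_lengths` (named
#'   integer vector).
#' @export
generate_annotation <- function(spec) {
  lay <- slot_layout(spec)
  if (spec$n_genes == 0) {
    return(list(genes = gene_annotation(character(), character(), integer(),
                                        integer() + 1L, character()),
                contig_lengths = lay$contig_lengths))
  }
  i <- seq_len(spec$n_genes)
  start <- lay$start[i] + 4000L
  genes <- gene_annotation(
    gene_id = sprintf("gene_%05d", i),
    chrom = lay$contig[i],
    start = start, end = start + spec$gene_length,
    strand = ifelse(i %% 2 == 1, "+", "-")
  )
  list(genes = genes, contig_lengths = lay$contig_lengths)
}

# NB counts for features x samples: mu = mu0 * per-feature donor factor *
# 2^lfc (in the feature's planted condition) * per-sample depth.
nb_counts <- function(mu0, lfc, diff_condition, samples, spec) {
  donors <- sort(unique(samples$donor))
  donor_fac <- matrix(exp(rnorm(length(mu0) * length(donors), 0, spec$donor_sd)),
                      length(mu0), dimnames = list(NULL, donors))
  depth <- exp(rnorm(nrow(samples), 0, spec$depth_sd))
  m <- matrix(0L, length(mu0), nrow(samples))
  for (s in seq_len(nrow(samples))) {
    fc <- ifelse(!is.na(diff_condition) & diff_condition == samples$condition[s],
                 2^lfc, 1)
    mu <- mu0 * donor_fac[, samples$donor[s]] * fc * depth[s]
    m[, s] <- if (spec$nb_dispersion > 0) {
      rnbinom(length(mu0), mu = mu, size = 1 / spec$nb_dispersion)
    } else {
      stats::rpois(length(mu0), mu)
    }
  }
  colnames(m) <- samples$sample_id
  m
}

#' Sample sheets of the simulated study
#'
#' @param spec a [simulation_spec()].
#' @return data.frame sample sheet (ATAC: donors x conditions x replicates;
#'   RNA: donors x conditions).
#' @export
atac_sample_sheet <- function(spec) {
  g <- expand.grid(rep = seq_len(spec$n_atac_replicates),
                   condition = CONDITIONS,
                   donor = paste0("D", seq_len(spec$n_donors)),
                   stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("ATAC_%s_%s_r%d", g$donor, g$condition, g$rep),
    donor = g$donor, condition = g$condition, assay = "ATAC",
    stringsAsFactors = FALSE
  )
}

#' @rdname atac_sample_sheet
#' @export
rna_sample_sheet <- function(spec) {
  g <- expand.grid(condition = CONDITIONS,
                   donor = paste0("D", seq_len(spec$n_donors)),
                   stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("RNA_%s_%s", g$donor, g$condition),
    donor = g$donor, condition = g$condition, assay = "RNA",
    stringsAsFactors = FALSE
  )
}

#' Generate ATAC peaks, per-sample calls, counts and the truth table
#'
#' Plants `n_peaks` true peaks (one per slot; `frac_distal` of them distal
#' by placement), assigns `frac_differential` a condition effect, draws
#' per-sample peak calls with jittered coordinates and per-peak call
#' probability, builds a small blacklist, and draws NB counts per true
#' peak.
#'
#' @param spec a [simulation_spec()].
#' @param annotation output of [generate_annotation()].
#' @return list: `calls` (`GRanges` with `sample_id`, `neglog10_p`),
#'   `counts` (`SummarizedExperiment` over true peaks), `truth`
#'   (data.frame), `blacklist` (`GRanges`), `samples` (ATAC sheet).
#' @export
generate_atac <- function(spec, annotation) {
  set.seed(spec$seed + 1L)
  lay <- slot_layout(spec)
  samples <- atac_sample_sheet(spec)
  n <- spec$n_peaks
  i <- seq_len(n)
  has_gene <- i <= spec$n_genes

  diff_idx <- sample(n, round(spec$frac_differential * n))
  is_diff <- seq_len(n) %in% diff_idx

  # differential peaks are placed distal more often than non-differential
  # ones, reproducing the observed distal skew of stimulation-responsive
  # regions; slots without a gene can only host distal peaks
  is_distal <- logical(n)
  for (grp in list(which(is_diff & has_gene), which(!is_diff & has_gene))) {
    fr <- if (length(grp) && is_diff[grp[1]]) spec$frac_distal_differential
          else spec$frac_distal
    if (length(grp)) is_distal[sample(grp, round(fr * length(grp)))] <- TRUE
  }
  is_distal[!has_gene] <- TRUE

  tss <- rep(NA_integer_, n)
  tss[has_gene] <- annotation$genes$tss[i[has_gene]]
  # distal zone: > 3 kb from every TSS and eRNA window clear of padded
  # gene boundaries, for either strand
  distal_lo <- spec$gene_length + 8000
  mid <- integer(n)
  mid[is_distal] <- lay$start[i[is_distal]] +
    as.integer(runif(sum(is_distal), distal_lo, 18000))
  mid[!is_distal] <- tss[!is_distal] +
    as.integer(runif(sum(!is_distal), -2500, 2500))
  half <- spec$peak_width %/% 2L

  diff_condition <- rep(NA_character_, n)
  diff_condition[diff_idx] <- sample(setdiff(CONDITIONS, "UT"), length(diff_idx),
                                     replace = TRUE)
  true_lfc <- numeric(n)
  mag <- pmax(rnorm(length(diff_idx), spec$planted_lfc, spec$lfc_sd), 0.5)
  true_lfc[diff_idx] <- mag * sample(c(-1, 1), length(diff_idx), replace = TRUE)

  call_prob <- rep(spec$call_prob_high, n)
  call_prob[sample(n, round(spec$frac_low_detect * n))] <- spec$call_prob_low
  blacklisted <- logical(n)
  blacklisted[sample(n, round(spec$frac_blacklist * n))] <- TRUE

  active <- logical(n)
  dist_idx <- which(is_distal)
  active[sample(dist_idx, round(spec$frac_erna_active * length(dist_idx)))] <- TRUE

  # planted eRNA log2 fold changes for active differential peaks: a
  # sign-mixture construction (a fraction of pairs concordant in direction,
  # the rest discordant, with correlated magnitudes) whose expected Pearson
  # correlation with the ATAC effect equals erna_atac_r. Because both
  # members keep magnitudes near planted_lfc, restricting to eRNAs that
  # pass the differential filter leaves the correlation essentially
  # unchanged, unlike an additive-noise construction.
  erna_lfc <- numeric(n)
  ad <- which(active & true_lfc != 0)
  if (length(ad)) {
    r <- spec$erna_atac_r
    L <- spec$planted_lfc; s2 <- spec$lfc_sd^2
    pi_agree <- min(1, max(0, (r * (L^2 + s2) / (L^2 + s2 * r) + 1) / 2))
    u <- (abs(true_lfc[ad]) - L) / spec$lfc_sd
    v <- r * u + sqrt(max(0, 1 - r^2)) * rnorm(length(ad))
    mag_e <- pmax(L + spec$lfc_sd * v, 0.5)
    s_e <- sign(true_lfc[ad]) *
      ifelse(runif(length(ad)) < pi_agree, 1, -1)
    erna_lfc[ad] <- s_e * mag_e
  }

  truth <- data.frame(
    peak_id = sprintf("tpeak_%05d", i),
    chrom = lay$contig[i],
    start = mid - half, end = mid + half, midpoint = mid,
    gene_id = ifelse(has_gene, sprintf("gene_%05d", i), NA_character_),
    is_distal = is_distal,
    diff_condition = diff_condition,
    true_lfc = true_lfc,
    is_erna_active = active,
    erna_lfc = erna_lfc,
    call_prob = call_prob,
    blacklisted = blacklisted,
    mu0 = 10^runif(n, spec$mean_count_log_range[1], spec$mean_count_log_range[2]),
    stringsAsFactors = FALSE
  )

  # per-sample calls with jittered edges and occasional weak significance
  calls <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    called <- which(runif(n) < call_prob)
    if (!length(called)) next
    js <- as.integer(runif(length(called), -50, 50))
    je <- as.integer(runif(length(called), -50, 50))
    weak <- runif(length(called)) < spec$frac_weak_call
    nlp <- ifelse(weak, runif(length(called), 1, 4.9),
                  runif(length(called), 6, 30))
    calls[[s]] <- genomic_intervals(
      truth$chrom[called],
      pmax(truth$start[called] + js, 0L),
      pmax(truth$end[called] + je, truth$start[called] + js + 50L),
      sample_id = samples$sample_id[s],
      neglog10_p = nlp
    )
  }
  calls <- do.call(c, calls[!vapply(calls, is.null, logical(1))])

  bl <- truth[truth$blacklisted, , drop = FALSE]
  blacklist <- if (nrow(bl)) {
    genomic_intervals(bl$chrom, pmax(bl$start - 100L, 0L), bl$end + 100L)
  } else GRanges()

  m <- nb_counts(truth$mu0, truth$true_lfc, truth$diff_condition, samples, spec)
  rownames(m) <- truth$peak_id
  list(calls = calls, counts = count_matrix(m, samples), truth = truth,
       blacklist = blacklist, samples = samples)
}

#' Generate RNA counts for genes and eRNA regions
#'
#' Genes linked to differential peaks (the peak's slot gene) inherit the
#' peak's planted effect (plus noise); further random genes are made
#' differential until `frac_differential` of genes carry an effect. eRNA
#' regions are the +-1 kb windows around distal true-peak midpoints;
#' active regions receive counts whose planted fold change follows the
#' correlated effect stored in the ATAC truth, inactive ones near-zero
#' background.
#'
#' @param spec a [simulation_spec()].
#' @param annotation output of [generate_annotation()].
#' @param truth ATAC truth table from [generate_atac()].
#' @return list: `gene_counts` (`SummarizedExperiment` with lengths),
#'   `erna_counts` (`SummarizedExperiment` over true eRNA regions),
#'   `gene_truth`, `erna_truth` (data.frames), `samples` (RNA sheet).
#' @export
generate_rna <- function(spec, annotation, truth) {
  set.seed(spec$seed + 2L)
  samples <- rna_sample_sheet(spec)
  genes <- annotation$genes
  ng <- nrow(genes)
  gene_lfc <- numeric(ng)
  gene_cond <- rep(NA_character_, ng)
  if (ng > 0) {
    inherit <- truth[!is.na(truth$gene_id) & truth$true_lfc != 0, , drop = FALSE]
    inherit <- inherit[!duplicated(inherit$gene_id), , drop = FALSE]
    gi <- match(inherit$gene_id, genes$gene_id)
    gene_lfc[gi] <- inherit$true_lfc + rnorm(length(gi), 0, 0.4)
    gene_cond[gi] <- inherit$diff_condition
    want <- round(spec$frac_differential * ng)
    extra <- setdiff(seq_len(ng), gi)
    n_extra <- max(0, min(want - length(gi), length(extra)))
    if (n_extra > 0) {
      ei <- sample(extra, n_extra)
      gene_cond[ei] <- sample(setdiff(CONDITIONS, "UT"), n_extra, replace = TRUE)
      gene_lfc[ei] <- pmax(rnorm(n_extra, spec$planted_lfc, spec$lfc_sd), 0.5) *
        sample(c(-1, 1), n_extra, replace = TRUE)
    }
    mu0 <- 10^runif(ng, spec$mean_count_log_range[1], spec$mean_count_log_range[2])
    gm <- nb_counts(mu0, gene_lfc, gene_cond, samples, spec)
    rownames(gm) <- genes$gene_id
    gene_counts <- count_matrix(gm, samples,
                                feature_lengths = setNames(genes$end - genes$start,
                                                           genes$gene_id))
  } else {
    gene_counts <- NULL
  }
  gene_truth <- data.frame(gene_id = genes$gene_id, diff_condition = gene_cond,
                           true_lfc = gene_lfc, stringsAsFactors = FALSE)

  et <- truth[truth$is_distal, , drop = FALSE]
  erna_mu0 <- ifelse(et$is_erna_active, 10^runif(nrow(et), 1.0, 2.0), 0.005)
  elfc <- ifelse(et$is_erna_active, et$erna_lfc, 0)
  em <- nb_counts(erna_mu0, elfc, et$diff_condition, samples, spec)
  rownames(em) <- paste0(et$peak_id, "_eRNA")
  erna_truth <- data.frame(
    region_id = rownames(em), peak_id = et$peak_id,
    is_erna_active = et$is_erna_active, erna_lfc = elfc,
    diff_condition = et$diff_condition, stringsAsFactors = FALSE
  )
  list(gene_counts = gene_counts, erna_counts = count_matrix(em, samples),
       gene_truth = gene_truth, erna_truth = erna_truth, samples = samples)
}

#' Generate the synthetic conservation track
#'
#' Per-base score = Gaussian baseline noise plus a Gaussian-shaped bump at
#' every true peak midpoint, with amplitude `amp_nondiff` at
#' non-differential and `amp_diff` at differential peaks; bases outside
#' peak neighbourhoods are uncovered (`NA`).
#'
#' @param spec a [simulation_spec()].
#' @param annotation output of [generate_annotation()] (contig lengths).
#' @param truth ATAC truth table.
#' @param pad covered half-window around each midpoint (default 1250 bp,
#'   enough for the +-1 kb profile window of slightly jittered consensus
#'   midpoints).
#' @return A [conservation_track()].
#' @export
generate_conservation <- function(spec, annotation, truth, pad = 1250) {
  set.seed(spec$seed + 3L)
  scores <- lapply(names(annotation$contig_lengths), function(ch) {
    len <- annotation$contig_lengths[[ch]]
    v <- rep(NA_real_, len)
    tt <- truth[truth$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(tt))) {
      amp <- if (tt$true_lfc[k] != 0) spec$amp_diff else spec$amp_nondiff
      lo <- max(tt$midpoint[k] - pad, 0L)
      hi <- min(tt$midpoint[k] + pad, len)
      off <- (lo:(hi - 1L)) - tt$midpoint[k]
      v[(lo + 1L):hi] <- rnorm(length(off), 0, spec$cons_noise_sd) +
        amp * exp(-off^2 / (2 * spec$cons_bump_sd^2))
    }
    Rle(v)
  })
  names(scores) <- names(annotation$contig_lengths)
  conservation_track(scores, annotation$contig_lengths)
}

# conditions represented in the simulated eQTL catalogue (the published
# monocyte catalogue covers naive, LPS2, LPS24 and IFNG states)
EQTL_CONDITIONS <- c("UT", "LPS2", "LPS24", "IFNG")

#' Generate the synthetic eQTL catalogue
#'
#' Places credible sets of 1-3 variants inside a fraction of detectable
#' peaks, linking each to the peak's slot gene. Each credible set has one
#' lead condition; for differential peaks the lead condition matches the
#' planted condition with probability `frac_context_eqtl` (when that
#' condition exists in the catalogue), otherwise it is drawn at random.
#' The lead variant is strongly significant in the lead condition and weak
#' elsewhere; non-lead credible-set members are significant but less so.
#'
#' @param spec a [simulation_spec()].
#' @param annotation output of [generate_annotation()].
#' @param truth ATAC truth table.
#' @return data.frame in [read_eqtl_tsv()] layout (0-based `pos`).
#' @export
generate_eqtl <- function(spec, annotation, truth) {
  set.seed(spec$seed + 4L)
  eligible <- which(!truth$blacklisted & truth$call_prob >= 0.5 &
                      !is.na(truth$gene_id))
  pick <- sort(sample(eligible, round(spec$frac_eqtl_peaks * length(eligible))))
  rows <- vector("list", length(pick))
  for (j in seq_along(pick)) {
    k <- pick[j]
    size <- sample(1:3, 1)
    pos <- sort(sample(truth$start[k]:(truth$end[k] - 1L), size))
    vid <- sprintf("rs_%s_%d", sub("tpeak_", "", truth$peak_id[k]), seq_len(size))
    cond <- truth$diff_condition[k]
    if (!is.na(cond) && cond %in% EQTL_CONDITIONS &&
        runif(1) < spec$frac_context_eqtl) {
      lead_cond <- cond
    } else {
      lead_cond <- sample(EQTL_CONDITIONS, 1)
    }
    lead_var <- sample(size, 1)
    per <- expand.grid(v = seq_len(size), condition = EQTL_CONDITIONS,
                       stringsAsFactors = FALSE)
    p <- 10^-runif(nrow(per), 0, 4.5)
    in_lead <- per$condition == lead_cond
    p[in_lead & per$v != lead_var] <- 10^-runif(sum(in_lead & per$v != lead_var), 5.2, 7.5)
    p[in_lead & per$v == lead_var] <- 10^-runif(1, 8, 12)
    rows[[j]] <- data.frame(
      variant_id = vid[per$v],
      chrom = truth$chrom[k],
      pos = pos[per$v],
      gene_id = truth$gene_id[k],
      condition = per$condition,
      p = p,
      beta = ifelse(truth$true_lfc[k] != 0, sign(truth$true_lfc[k]), 1) *
        runif(nrow(per), 0.1, 0.8),
      credible_set_id = paste0("cs_", truth$peak_id[k]),
      is_lead = in_lead & per$v == lead_var,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the complete study
#'
#' Runs every generator in order under the spec's seed and returns the full
#' bundle of inputs and truth tables.
#'
#' @param spec a [simulation_spec()].
#' @return list: `spec`, `annotation`, `atac`, `rna`, `conservation`,
#'   `eqtl`.
#' @export
simulate_study <- function(spec = simulation_spec()) {
  annotation <- generate_annotation(spec)
  atac <- generate_atac(spec, annotation)
  rna <- generate_rna(spec, annotation, atac$truth)
  conservation <- generate_conservation(spec, annotation, atac$truth)
  eqtl <- generate_eqtl(spec, annotation, atac$truth)
  list(spec = spec, annotation = annotation, atac = atac, rna = rna,
       conservation = conservation, eqtl = eqtl)
}
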