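# Synthetic community generator: paired shotgun-gene and 16S-OTU count
# tables from a latent community with known OTU <-> organism <-> MGS truth.
# Each organism has a log-normal abundance profile across samples; gene
# counts are Poisson draws proportional to abundance x gene length x depth,
# OTU counts proportional to abundance x 16S copy number x depth. Optional
# confounders reproduce the failure modes co-abundance linking must face:
# organism pairs with correlated abundance (ecological co-association or
# near-identical relatives) and accessory genes whose presence/absence
# varies across samples independently of the core genome.

#' Configuration for the synthetic community generator
#'
#' Defaults describe a gut-community-sized benchmark: 40 organisms profiled
#' across 138 samples, 80-150 catalog genes each (300-3000 nt), one to
#' three 16S OTUs per organism with copy numbers 1-4, a log-normal
#' abundance spread of sigma = 1.5 on the log scale, and per-sample depths
#' of 2e5 shotgun reads and 2e4 amplicon reads.
#'
#' @param n_organisms Number of organisms.
#' @param n_samples Number of samples.
#' @param genes_per_organism Inclusive integer range `c(lo, hi)`.
#' @param gene_length_range Inclusive gene length range in nt.
#' @param otus_per_organism Inclusive range of 16S OTUs per organism
#'   (multicopy operons diverge enough to be clustered apart).
#' @param copy_number_range Inclusive range of per-OTU 16S copy numbers.
#' @param log_abundance_sigma Standard deviation of the organism latent
#'   log-abundance across samples (natural-log scale).
#' @param shotgun_depth Shotgun reads per sample; scalar or one value per
#'   sample.
#' @param amplicon_depth 16S amplicon reads per sample; scalar or one per
#'   sample.
#' @param n_confounded_pairs Organism pairs given correlated latent
#'   abundance with correlation `rho_conf` (ecological co-association).
#' @param rho_conf Latent correlation of confounded pairs.
#' @param n_near_relatives Organism pairs modelling close relatives sharing
#'   a niche, with latent correlation `rho_rel`.
#' @param rho_rel Latent correlation of near-relative pairs.
#' @param accessory_fraction Fraction of each organism's genes given an
#'   independent per-sample presence/absence pattern.
#' @param accessory_prevalence Probability an accessory gene is present in a
#'   given sample.
#' @param overdispersion Gamma shape parameter for optional negative
#'   binomial counts; `Inf` (default) gives pure Poisson noise.
#' @param seed Integer seed; generation is fully reproducible given it.
#' @return Validated configuration list of class `"community_config"`.
#' @export
community_config <- function(n_organisms = 40,
                             n_samples = 138,
                             genes_per_organism = c(80, 150),
                             gene_length_range = c(300, 3000),
                             otus_per_organism = c(1, 3),
                             copy_number_range = c(1, 4),
                             log_abundance_sigma = 1.5,
                             shotgun_depth = 2e5,
                             amplicon_depth = 2e4,
                             n_confounded_pairs = 0,
                             rho_conf = 0.99,
                             n_near_relatives = 0,
                             rho_rel = 0.9,
                             accessory_fraction = 0.1,
                             accessory_prevalence = 0.5,
                             overdispersion = Inf,
                             seed = 1L) {
  cfg <- list(n_organisms = n_organisms, n_samples = n_samples,
              genes_per_organism = genes_per_organism,
              gene_length_range = gene_length_range,
              otus_per_organism = otus_per_organism,
              copy_number_range = copy_number_range,
              log_abundance_sigma = log_abundance_sigma,
              shotgun_depth = shotgun_depth, amplicon_depth = amplicon_depth,
              n_confounded_pairs = n_confounded_pairs, rho_conf = rho_conf,
              n_near_relatives = n_near_relatives, rho_rel = rho_rel,
              accessory_fraction = accessory_fraction,
              accessory_prevalence = accessory_prevalence,
              overdispersion = overdispersion, seed = seed)
  rng <- function(x) length(x) == 2 && x[1] >= 1 && x[1] <= x[2] &&
    all(x == round(x))
  stopifnot(n_organisms >= 1, n_samples >= 1,
            rng(genes_per_organism), rng(gene_length_range),
            rng(otus_per_organism), rng(copy_number_range),
            log_abundance_sigma >= 0,
            all(shotgun_depth >= 1), all(amplicon_depth >= 1),
            n_confounded_pairs >= 0, n_near_relatives >= 0,
            rho_conf >= -1, rho_conf <= 1, rho_rel >= -1, rho_rel <= 1,
            accessory_fraction >= 0, accessory_fraction <= 1,
            accessory_prevalence >= 0, accessory_prevalence <= 1,
            overdispersion > 0)
  if (2 * (n_confounded_pairs + n_near_relatives) > n_organisms) {
    stop("not enough organisms for the requested correlated pairs",
         call. = FALSE)
  }
  for (d in c("shotgun_depth", "amplicon_depth")) {
    if (!(length(cfg[[d]]) %in% c(1, n_samples))) {
      stop(d, " must be a scalar or one value per sample", call. = FALSE)
    }
  }
  structure(cfg, class = "community_config")
}

# Draw one count matrix: Poisson, or gamma-Poisson (negative binomial) when
# overdispersion is finite.
draw_counts <- function(rate, overdispersion) {
  n <- length(rate)
  if (is.finite(overdispersion)) {
    rate <- rate * stats::rgamma(n, shape = overdispersion,
                                 rate = overdispersion)
  }
  matrix(stats::rpois(n, rate), nrow = nrow(rate),
         dimnames = dimnames(rate))
}

#' Generate a synthetic community with known OTU-MGS truth
#'
#' Produces paired shotgun-gene and 16S-OTU count tables from one latent
#' community. Per sample `s` and organism `o`: latent abundance
#' `a(o,s) ~ lognormal(0, sigma^2)`, i.i.d. across organisms and samples
#' except for configured confounded / near-relative pairs, which are drawn
#' from a bivariate log-normal with the configured correlation; relative
#' abundance `p(o,s) = a(o,s) / sum_o' a(o',s)`. A core gene `g` of
#' organism `o` receives `count(g,s) ~ Poisson(depth(s) * w / W(s))` with
#' weight `w = p(o,s) * length(g)` and `W(s)` the per-sample total weight;
#' an accessory gene's weight is additionally multiplied by an independent
#' Bernoulli presence indicator. OTU counts follow the same construction
#' with `length` replaced by the 16S copy number. Membership maps every
#' gene of organism `o` — accessory genes included, deliberately: they are
#' the hard case tracer selection must demote — to MGS id `MGS_<o>`.
#'
#' @param config A [community_config()].
#' @return List with `gene_counts`, `gene_lengths`, `membership`,
#'   `otu_counts`, and `truth` (class `"synthetic_truth"`: per-organism
#'   genes, OTUs, latent vector and partner, plus the config).
#' @export
generate_community <- function(config) {
  if (!inherits(config, "community_config")) {
    stop("config must come from community_config()", call. = FALSE)
  }
  cfg <- config
  with_seed(cfg$seed, {
    org_ids <- sprintf("org%03d", seq_len(cfg$n_organisms))
    samples <- sprintf("s%03d", seq_len(cfg$n_samples))

    # latent log-abundance, i.i.d. N(0, sigma^2) then pairwise correlated
    z <- matrix(stats::rnorm(cfg$n_organisms * cfg$n_samples,
                             sd = cfg$log_abundance_sigma),
                nrow = cfg$n_organisms, dimnames = list(org_ids, samples))
    partner <- stats::setNames(rep(NA_character_, cfg$n_organisms), org_ids)
    partner_type <- stats::setNames(rep(NA_character_, cfg$n_organisms), org_ids)
    n_pairs <- cfg$n_confounded_pairs + cfg$n_near_relatives
    if (n_pairs > 0) {
      chosen <- sample(cfg$n_organisms, 2 * n_pairs)
      for (p in seq_len(n_pairs)) {
        i <- chosen[2 * p - 1]
        j <- chosen[2 * p]
        rho <- if (p <= cfg$n_confounded_pairs) cfg$rho_conf else cfg$rho_rel
        type <- if (p <= cfg$n_confounded_pairs) "confounded" else "near_relative"
        z[j, ] <- rho * z[i, ] + sqrt(1 - rho^2) *
          stats::rnorm(cfg$n_samples, sd = cfg$log_abundance_sigma)
        partner[c(i, j)] <- org_ids[c(j, i)]
        partner_type[c(i, j)] <- type
      }
    }
    latent <- exp(z)
    p_rel <- sweep(latent, 2, colSums(latent), "/")

    # genes
    n_genes <- sample_range(cfg$genes_per_organism, cfg$n_organisms)
    gene_org <- rep(seq_len(cfg$n_organisms), n_genes)
    gene_ids <- unlist(lapply(seq_len(cfg$n_organisms), function(i) {
      sprintf("%s_g%04d", org_ids[i], seq_len(n_genes[i]))
    }), use.names = FALSE)
    gene_len <- sample_range(cfg$gene_length_range, length(gene_ids))
    accessory <- unlist(lapply(seq_len(cfg$n_organisms), function(i) {
      k <- floor(cfg$accessory_fraction * n_genes[i])
      acc <- rep(FALSE, n_genes[i])
      if (k > 0) acc[sample(n_genes[i], k)] <- TRUE
      acc
    }), use.names = FALSE)

    weight <- p_rel[gene_org, , drop = FALSE] * gene_len
    if (any(accessory)) {
      n_acc <- sum(accessory)
      present <- matrix(stats::rbinom(n_acc * cfg$n_samples, 1,
                                      cfg$accessory_prevalence),
                        nrow = n_acc)
      weight[accessory, ] <- weight[accessory, , drop = FALSE] * present
    }
    wtot <- colSums(weight)
    wtot[wtot == 0] <- 1
    gene_rate <- sweep(weight, 2, cfg$shotgun_depth / wtot, "*")
    dimnames(gene_rate) <- list(gene_ids, samples)
    gene_counts <- draw_counts(gene_rate, cfg$overdispersion)

    # OTUs
    n_otus <- sample_range(cfg$otus_per_organism, cfg$n_organisms)
    otu_org <- rep(seq_len(cfg$n_organisms), n_otus)
    otu_ids <- unlist(lapply(seq_len(cfg$n_organisms), function(i) {
      sprintf("%s_otu%d", org_ids[i], seq_len(n_otus[i]))
    }), use.names = FALSE)
    copy_number <- sample_range(cfg$copy_number_range, length(otu_ids))
    ow <- p_rel[otu_org, , drop = FALSE] * copy_number
    owt <- colSums(ow)
    owt[owt == 0] <- 1
    otu_rate <- sweep(ow, 2, cfg$amplicon_depth / owt, "*")
    dimnames(otu_rate) <- list(otu_ids, samples)
    otu_counts <- draw_counts(otu_rate, cfg$overdispersion)

    organisms <- lapply(seq_len(cfg$n_organisms), function(i) {
      gi <- gene_org == i
      oi <- otu_org == i
      list(organism_id = org_ids[i],
           mgs_id = paste0("MGS_", org_ids[i]),
           genes = data.frame(gene_id = gene_ids[gi],
                              length_nt = gene_len[gi],
                              accessory = accessory[gi],
                              stringsAsFactors = FALSE),
           otus = data.frame(otu_id = otu_ids[oi],
                             copy_number = copy_number[oi],
                             stringsAsFactors = FALSE),
           latent = latent[i, ],
           partner = unname(partner[i]),
           partner_type = unname(partner_type[i]))
    })
    names(organisms) <- org_ids

    list(gene_counts = gene_counts,
         gene_lengths = gene_length_table(gene_ids, gene_len),
         membership = membership_table(gene_ids,
                                       paste0("MGS_", org_ids[gene_org])),
         otu_counts = otu_counts,
         truth = structure(list(organisms = organisms, config = cfg),
                           class = "synthetic_truth"))
  })
}

# Uniform integer draw from an inclusive range.
sample_range <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' True OTU-MGS pairs of a synthetic community
#'
#' One pair per OTU, mapping it to its organism's MGS id — the answer key
#' for [evaluate_recovery()]. Organisms with multiple OTUs (multicopy 16S)
#' contribute multiple pairs to the same MGS.
#'
#' @param truth `"synthetic_truth"` object from [generate_community()].
#' @return data.frame with columns `otu_id`, `mgs_id`.
#' @export
truth_links <- function(truth) {
  if (!inherits(truth, "synthetic_truth")) {
    stop("truth must come from generate_community()", call. = FALSE)
  }
  rows <- lapply(truth$organisms, function(o) {
    if (nrow(o$otus) == 0) return(NULL)
    data.frame(otu_id = o$otus$otu_id, mgs_id = o$mgs_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(otu_id = character(0), mgs_id = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
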