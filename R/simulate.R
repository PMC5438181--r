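#' Configuration of the synthetic dataset generator
#'
#' Captures the study conditions emulated by [simulate_crcc_dataset()]:
#' species-specific codon usage (one Dirichlet draw per synonymous set per
#' species), per-gene %GC3 heterogeneity (Beta-distributed targets reached
#' by exponential tilting of third-position G/C), optional universal codon
#' pair bias (log-normal per-pair multipliers shared across species),
#' homolog families with a conserved core, star-phylogeny substitutions and
#' geometric terminal extensions (producing gapped termini), and planted
#' rare codon clusters at chosen alignment columns in a chosen fraction of
#' species.
#'
#' @param n_species Number of species (default 20).
#' @param n_families Number of homolog families (default 50).
#' @param background_genes Extra non-family genes per species, stabilising
#'   usage tables and %GC3 bins (default 30).
#' @param core_length Range of ancestor (core) protein lengths (default
#'   220-320 residues).
#' @param background_length Range of background gene lengths (residues).
#' @param identity Expected amino-acid identity between a member and the
#'   family ancestor outside planted windows (default 0.85).
#' @param dirichlet_conc Dirichlet concentration of within-set codon
#'   frequencies; values below 1 give skewed, realistic usage (default 0.5).
#' @param gc3_shape Beta shape parameters of per-gene target %GC3
#'   (default c(8, 8): mean 50%, sd about 12 points).
#' @param pair_bias_sd Standard deviation of log pair multipliers; 0
#'   disables codon pair bias (default 0).
#' @param usage_temp_range Range of the per-gene codon-adaptation
#'   temperature: within-set codon probabilities are raised to a power
#'   drawn uniformly from this range (1 = fully adapted to the species
#'   table, values near 0 = nearly neutral synonymous choice). Emulates
#'   the variation in translational adaptation across genes that makes
#'   rare codon clusters common in real ORFeomes (default c(0, 0.5),
#'   giving roughly a fifth to a quarter of windows a negative score).
#' @param plant_frac Fraction of families receiving a planted rare codon
#'   cluster (default 0.6).
#' @param plant_depth Probability that a planted-window codon is forced to
#'   the rare side of its synonymous set (default 0.8).
#' @param carrier_frac Fraction of species carrying the plant (default 0.8).
#' @param plant_width Planted window width in codons (default 17, one
#'   %MinMax window).
#' @param terminal_ext_mean Mean geometric length of N-/C-terminal
#'   extensions per member (default 25 residues).
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 20L, n_families = 50L, background_genes = 30L,
                       core_length = c(220L, 320L), background_length = c(150L, 450L),
                       identity = 0.85, dirichlet_conc = 0.5, gc3_shape = c(8, 8),
                       pair_bias_sd = 0, usage_temp_range = c(0, 0.5),
                       plant_frac = 0.6, plant_depth = 0.8,
                       carrier_frac = 0.8, plant_width = 17L,
                       terminal_ext_mean = 25, seed) {
  if (missing(seed)) abort("sim_config(): seed is mandatory")
  stopifnot(
    plant_frac >= 0, plant_frac <= 1, plant_depth >= 0, plant_depth <= 1,
    carrier_frac >= 0, carrier_frac <= 1, plant_width >= 1, identity >= 0, identity <= 1
  )
  structure(
    list(
      n_species = as.integer(n_species), n_families = as.integer(n_families),
      background_genes = as.integer(background_genes),
      core_length = as.integer(core_length), background_length = as.integer(background_length),
      identity = identity, dirichlet_conc = dirichlet_conc, gc3_shape = gc3_shape,
      pair_bias_sd = pair_bias_sd, usage_temp_range = usage_temp_range,
      plant_frac = plant_frac, plant_depth = plant_depth,
      carrier_frac = carrier_frac, plant_width = as.integer(plant_width),
      terminal_ext_mean = terminal_ext_mean, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Draw species codon-usage parameters
#'
#' For every species and every synonymous set, within-set codon frequencies
#' are drawn from a symmetric Dirichlet with the configured concentration;
#' amino-acid usage is uniform. Concentrations below 1 yield skewed sets
#' with a strict rare/common ordering almost surely.
#'
#' @param config A `sim_config` (its `seed` seeds the draw locally).
#' @return A named list (by species `sp01`, `sp02`, ...) of tibbles with
#'   columns `codon`, `amino_acid`, `p_within_aa`.
#' @export
simulate_usage_tables <- function(config) {
  with_seed_local(config$seed, draw_usage_tables(config))
}

draw_usage_tables <- function(config) {
  species <- sprintf("sp%02d", seq_len(config$n_species))
  out <- lapply(species, function(sp) {
    p <- numeric(length(.SENSE))
    for (s in .SYN_SETS) {
      g <- rgamma(length(s), shape = config$dirichlet_conc)
      while (sum(g) == 0) g <- rgamma(length(s), shape = config$dirichlet_conc)
      p[s] <- g / sum(g)
    }
    tibble(codon = .SENSE, amino_acid = .SENSE_AA, p_within_aa = p)
  })
  setNames(out, species)
}

# Solve the tilt lambda so the gene's expected %GC3 matches target g.
# p_within: 61-vector of within-set probabilities; aa_counts: named counts
# of amino acids in the gene.
solve_gc3_tilt <- function(p_within, aa_counts, g) {
  sets <- .SYN_SETS[names(aa_counts)]
  expected <- function(lam) {
    e <- vapply(sets, function(s) {
      w <- p_within[s] * exp(lam * .IS_GC3[s])
      sum(w * .IS_GC3[s]) / sum(w)
    }, numeric(1))
    sum(e * aa_counts) / sum(aa_counts)
  }
  lo <- -10
  hi <- 10
  if (expected(lo) >= g) return(lo)
  if (expected(hi) <= g) return(hi)
  uniroot(function(l) expected(l) - g, c(lo, hi), tol = 1e-4)$root
}

# Temper within-set probabilities: p^tau renormalised per synonymous set.
# tau = 1 keeps the species table; tau -> 0 approaches neutral choice.
temper_within <- function(p_within, tau) {
  out <- p_within
  for (s in .SYN_SETS) {
    w <- p_within[s]^tau
    out[s] <- w / sum(w)
  }
  out
}

# Encode an amino-acid sequence for one species/gene: tempered, GC3-tilted
# base weights + shared pair-bias multipliers, sampled 3'->5'.
encode_gene <- function(aa, p_within, g_target, bias_mult, tau = 1) {
  if (tau != 1) p_within <- temper_within(p_within, tau)
  counts <- table(aa)
  lam <- solve_gc3_tilt(p_within, counts, g_target)
  w <- p_within * exp(lam * .IS_GC3)
  sample_codons_chain(.SYN_SETS[aa], w, bias_mult)
}

# Precompute per-species rare-side draws: for each amino acid, the codons
# below the set mean of within-set probability, weighted toward the rarest
# (inverse within-set probability), so a full-depth plant approaches the
# all-rarest encoding (%MinMax near -100).
rare_side_sets <- function(p_within) {
  lapply(.SYN_SETS, function(s) {
    p <- p_within[s]
    r <- s[p < mean(p)]
    list(idx = r, w = 1 / pmax(p_within[r], 1e-12))
  })
}

#' Simulate one homolog family
#'
#' Draws an ancestor protein, derives one member per species by i.i.d.
#' substitutions (planted window conserved) plus random terminal
#' extensions, encodes every member with its species codon usage, per-gene
#' %GC3 tilt and the shared pair-bias multipliers, and optionally plants a
#' rare codon cluster: in carrier species, each codon of the planted window
#' is forced to the rare side of its synonymous set with probability
#' `plant_depth`. The alignment is produced from the known residue homology
#' (terminal extensions right-/left-aligned against the conserved core), so
#' no external aligner is involved.
#'
#' @param config A `sim_config`.
#' @param tables Usage parameter list from [simulate_usage_tables()].
#' @param bias_mult 61 x 61 matrix of true pair multipliers (all 1 for no
#'   bias).
#' @param family_id Family identifier.
#' @param planted Logical: plant a conserved rare codon cluster?
#' @return A list: `family` (a `homolog_family` whose members carry `cds`),
#'   `truth` (one-row tibble: `family_id`, `planted`, `plant_column`,
#'   `n_carriers`), `records` (ORF-record rows of the member genes). Uses
#'   the current RNG stream (callers seed).
#' @export
simulate_family <- function(config, tables, bias_mult, family_id, planted) {
  species <- names(tables)
  n <- length(species)
  Lc <- sample(config$core_length[1]:config$core_length[2], 1L)
  anc <- sample(.AA20, Lc, replace = TRUE)
  w <- config$plant_width
  margin <- 60L
  plant_start <- NA_integer_
  carriers <- character(0)
  if (planted) {
    lo <- margin
    hi <- Lc - margin - w + 1L
    if (hi < lo) abort("simulate_family(): core too short for an interior plant")
    plant_start <- sample(lo:hi, 1L)
    carriers <- sample(species, max(1L, round(config$carrier_frac * n)))
  }
  plant_pos <- if (planted) plant_start:(plant_start + w - 1L) else integer(0)

  next_l <- rgeom_mean(n, config$terminal_ext_mean)
  cext_l <- rgeom_mean(n, config$terminal_ext_mean)
  emax <- max(next_l)
  cmax <- max(cext_l)

  members <- vector("list", n)
  for (k in seq_len(n)) {
    sp <- species[k]
    pw <- tables[[sp]]$p_within_aa
    core <- anc
    sub_at <- runif(Lc) < (1 - config$identity)
    sub_at[plant_pos] <- FALSE
    if (any(sub_at)) core[sub_at] <- sample(.AA20, sum(sub_at), replace = TRUE)
    aa_full <- c(
      sample(.AA20, next_l[k], replace = TRUE),
      core,
      sample(.AA20, cext_l[k], replace = TRUE)
    )
    g <- rbeta(1, config$gc3_shape[1], config$gc3_shape[2])
    tau <- runif(1, config$usage_temp_range[1], config$usage_temp_range[2])
    idx <- encode_gene(aa_full, pw, g, bias_mult, tau)
    if (planted && sp %in% carriers && config$plant_depth > 0) {
      rs <- rare_side_sets(pw)
      for (p in plant_pos) {
        full_p <- next_l[k] + p
        set <- rs[[aa_full[full_p]]]
        if (length(set$idx) > 0 && runif(1) < config$plant_depth) {
          idx[full_p] <- if (length(set$idx) == 1L) set$idx else sample(set$idx, 1L, prob = set$w)
        }
      }
    }
    aligned <- paste(
      c(
        rep("-", emax - next_l[k]), aa_full,
        rep("-", cmax - cext_l[k])
      ),
      collapse = ""
    )
    members[[k]] <- tibble(
      species_id = sp,
      gene_id = paste0(family_id, "_", sp),
      aligned = aligned,
      cds = paste(.SENSE[idx], collapse = ""),
      protein = paste(aa_full, collapse = "")
    )
  }
  members <- bind_rows(members)
  fam <- homolog_family(family_id, members)
  list(
    family = fam,
    truth = tibble(
      family_id = family_id,
      planted = planted,
      plant_column = if (planted) emax + plant_start else NA_integer_,
      n_carriers = length(carriers),
      carriers = paste(carriers, collapse = ",")
    ),
    records = members[, c("gene_id", "species_id", "cds", "protein")]
  )
}

# Geometric lengths with the requested mean (mean 0 gives all-zero).
rgeom_mean <- function(n, mean_len) {
  if (mean_len <= 0) return(integer(n))
  rgeom(n, 1 / (1 + mean_len))
}

#' Simulate a full synthetic dataset with known ground truth
#'
#' Generates species ORFeomes (family member genes plus background genes)
#' and homolog families under the conditions in `config`, fully
#' deterministic under `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A list of class `crcc_dataset`: `orfeomes` (ORF-record tibble
#'   over all species), `families` (list of `homolog_family`), `truth`
#'   (per-family tibble with planted columns), `tables` (true usage
#'   parameters), `bias_mult` (true pair multipliers) and `config`.
#' @export
simulate_crcc_dataset <- function(config) {
  with_seed_local(config$seed, {
    tables <- draw_usage_tables(config)
    nc <- length(.SENSE)
    bias_mult <- matrix(1, nc, nc, dimnames = list(.SENSE, .SENSE))
    if (config$pair_bias_sd > 0) {
      bias_mult[] <- exp(rnorm(nc * nc, 0, config$pair_bias_sd))
    }
    n_plant <- round(config$plant_frac * config$n_families)
    planted <- seq_len(config$n_families) <= n_plant
    fams <- vector("list", config$n_families)
    truth <- vector("list", config$n_families)
    recs <- vector("list", config$n_families)
    for (i in seq_len(config$n_families)) {
      fid <- sprintf("fam%03d", i)
      sim <- simulate_family(config, tables, bias_mult, fid, planted[i])
      fams[[i]] <- sim$family
      truth[[i]] <- sim$truth
      recs[[i]] <- sim$records
    }
    bg <- lapply(names(tables), function(sp) {
      if (config$background_genes == 0L) return(NULL)
      pw <- tables[[sp]]$p_within_aa
      rows <- lapply(seq_len(config$background_genes), function(j) {
        len <- sample(config$background_length[1]:config$background_length[2], 1L)
        aa <- sample(.AA20, len, replace = TRUE)
        g <- rbeta(1, config$gc3_shape[1], config$gc3_shape[2])
        tau <- runif(1, config$usage_temp_range[1], config$usage_temp_range[2])
        idx <- encode_gene(aa, pw, g, bias_mult, tau)
        tibble(
          gene_id = sprintf("%s_bg%03d", sp, j), species_id = sp,
          cds = paste(.SENSE[idx], collapse = ""),
          protein = paste(aa, collapse = "")
        )
      })
      bind_rows(rows)
    })
    structure(
      list(
        orfeomes = bind_rows(bind_rows(recs), bind_rows(bg)),
        families = setNames(fams, vapply(fams, function(f) f$family_id, character(1))),
        truth = bind_rows(truth),
        tables = tables,
        bias_mult = bias_mult,
        config = config
      ),
      class = "crcc_dataset"
    )
  })
}

#' Write a synthetic dataset to disk in pipeline input formats
#'
#' Emits one nucleotide FASTA per species under `orfeomes/`, a family
#' membership TSV (`families.tsv`), one aligned protein FASTA per family
#' under `alignments/` (headers `species_id|gene_id`), and the ground-truth
#' table (`truth.tsv`).
#'
#' @param dataset A `crcc_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_crcc_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "orfeomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  for (sp in unique(dataset$orfeomes$species_id)) {
    rows <- dataset$orfeomes[dataset$orfeomes$species_id == sp, ]
    x <- Biostrings::DNAStringSet(setNames(rows$cds, rows$gene_id))
    Biostrings::writeXStringSet(x, file.path(dir, "orfeomes", paste0(sp, ".fasta")))
  }
  membership <- bind_rows(lapply(dataset$families, function(f) {
    tibble(family_id = f$family_id, species_id = f$members$species_id, gene_id = f$members$gene_id)
  }))
  readr::write_tsv(membership, file.path(dir, "families.tsv"))
  for (f in dataset$families) {
    x <- Biostrings::AAStringSet(setNames(f$members$aligned, paste(f$members$species_id, f$members$gene_id, sep = "|")))
    Biostrings::writeXStringSet(x, file.path(dir, "alignments", paste0(f$family_id, ".fasta")))
  }
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Load a dataset from the on-disk layout written by [emit_crcc_dataset()]
#'
#' @param dir Dataset directory.
#' @param seed Optional seed for paralog filtering draws (unused for
#'   datasets that already have one member per species).
#' @return A `crcc_dataset` (without generator internals; `truth` present
#'   when `truth.tsv` exists).
#' @export
load_crcc_dataset <- function(dir, seed = NULL) {
  fasta <- list.files(file.path(dir, "orfeomes"), pattern = "\\.fasta$", full.names = TRUE)
  if (length(fasta) == 0) abort(paste0("no ORFeome FASTA files under ", dir))
  orfeomes <- bind_rows(lapply(fasta, read_orfeome, quiet = TRUE))
  membership <- readr::read_tsv(file.path(dir, "families.tsv"), show_col_types = FALSE)
  fams <- lapply(split(membership, membership$family_id), function(mem) {
    load_family(mem, file.path(dir, "alignments", paste0(mem$family_id[1], ".fasta")),
      orfeomes,
      seed = seed
    )
  })
  fams <- fams[!vapply(fams, is.null, logical(1))]
  truth_path <- file.path(dir, "truth.tsv")
  structure(
    list(
      orfeomes = orfeomes,
      families = fams,
      truth = if (file.exists(truth_path)) readr::read_tsv(truth_path, show_col_types = FALSE) else NULL,
      config = NULL
    ),
    class = "crcc_dataset"
  )
}
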