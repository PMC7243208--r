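#' Simulation configuration
#'
#' Bundles all knobs of the founder-mosaic simulator. Defaults emulate the
#' cohort the package is designed around: ~1331 phenotyped animals,
#' high-density chip spacing (~3.8 kb), LD decaying over tens of kb
#' (r-squared dropping below 0.2 around 34 kb), genes covering roughly a
#' third of the genome with nested exon/CDS/UTR structure, moderate
#' heritability (0.4), and environmental fixed effects (sex, year, entry
#' body weight, days on feed) explaining about a fifth of the phenotypic
#' variance.
#'
#' @param n_individuals Number of diploid individuals.
#' @param n_chromosomes,markers_per_chrom,chrom_length Genome layout.
#' @param ld_decay Per-bp haplotype-copy switch rate of the founder mosaic;
#'   0 means every gamete is an exact founder copy.
#' @param n_founders Size of the founder haplotype pool per chromosome.
#' @param n_genes Genes per chromosome.
#' @param gene_length,exon_length Min/max feature lengths in bp.
#' @param exons_per_gene Min/max exon count per gene.
#' @param architecture Genetic architecture of the trait: additive SNP
#'   effects, multi-allelic haplotype-window QTL, pairwise epistatic
#'   (genotype-combination) QTL, or an equal-variance mix of the first two.
#' @param n_qtl Number of QTL (for `epistatic`, `n_qtl %/% 2` locus pairs).
#' @param qtl_window Min/max markers per haplotype-QTL window.
#' @param qtl_class_bias Fraction of QTL placed inside gene features.
#' @param h2_target Target narrow-sense heritability of the adjusted trait.
#' @param sex_levels,year_levels Factor level counts for the fixed effects.
#' @param fixed_sd Standard deviation of each fixed-effect component on the
#'   unit-genetic-variance scale (0.25 puts ~20% of the phenotypic variance
#'   into fixed effects).
#' @param seed Integer seed; full determinism of all emitted data.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1331,
                       n_chromosomes = 5,
                       markers_per_chrom = 400,
                       chrom_length = 1.5e6,
                       ld_decay = 6e-6,
                       n_founders = 30,
                       n_genes = 40,
                       gene_length = c(4000, 20000),
                       exons_per_gene = c(1, 4),
                       exon_length = c(200, 2000),
                       architecture = c("snp_additive", "haplotype_qtl",
                                        "epistatic", "mixed"),
                       n_qtl = 100,
                       qtl_window = c(3, 5),
                       qtl_class_bias = 0.5,
                       h2_target = 0.4,
                       sex_levels = 2,
                       year_levels = 8,
                       fixed_sd = 0.25,
                       seed = 1) {
  architecture <- match.arg(architecture)
  stopifnot(h2_target > 0, h2_target < 1,
            qtl_class_bias >= 0, qtl_class_bias <= 1,
            markers_per_chrom <= chrom_length,
            n_individuals >= 2, n_founders >= 2, ld_decay >= 0)
  structure(
    list(n_individuals = n_individuals, n_chromosomes = n_chromosomes,
         markers_per_chrom = markers_per_chrom, chrom_length = chrom_length,
         ld_decay = ld_decay, n_founders = n_founders, n_genes = n_genes,
         gene_length = gene_length, exons_per_gene = exons_per_gene,
         exon_length = exon_length, architecture = architecture,
         n_qtl = n_qtl, qtl_window = qtl_window,
         qtl_class_bias = qtl_class_bias, h2_target = h2_target,
         sex_levels = sex_levels, year_levels = year_levels,
         fixed_sd = fixed_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Chromosome lengths of a simulated genome
#'
#' @param cfg A [sim_config()].
#' @return Named integer vector (`chr1`, `chr2`, ...).
#' @export
sim_chrom_lengths <- function(cfg) {
  stats::setNames(rep(as.integer(cfg$chrom_length), cfg$n_chromosomes),
                  paste0("chr", seq_len(cfg$n_chromosomes)))
}

#' Simulate phased genotypes with distance-decaying LD
#'
#' Each chromosome carries a pool of founder haplotypes with per-marker
#' allele frequencies drawn uniformly on (0.01, 0.5). Founder alleles are
#' correlated along the chromosome through a Gaussian-copula first-order
#' autoregression whose latent correlation decays as
#' `exp(-ld_decay * distance)`, so the pool itself shows chip-like
#' short-range linkage disequilibrium. Every sampled gamete is then a
#' mosaic of founders: walking along the markers, the copied founder
#' switches between adjacent markers with probability
#' `1 - exp(-ld_decay * distance)`. Together the two mechanisms give LD
#' that decays smoothly with physical distance; the default `ld_decay`
#' puts r-squared near 0.2 at about 34 kb, the decay profile of a dense
#' bovine chip cohort.
#'
#' @param cfg A [sim_config()].
#' @return A [phased_genotypes] object (markers may be monomorphic in small
#'   samples; run [apply_qc()] as with real data).
#' @export
simulate_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_individuals
    hap_list1 <- list()
    hap_list2 <- list()
    mk <- list()
    for (cc in seq_len(cfg$n_chromosomes)) {
      m <- cfg$markers_per_chrom
      pos <- sort(sample.int(cfg$chrom_length, m))
      freq <- stats::runif(m, 0.01, 0.5)
      # founders: latent AR(1) Gaussian thresholded at the target frequency
      z <- matrix(stats::rnorm(cfg$n_founders * m), nrow = cfg$n_founders)
      if (m > 1L) {
        ar <- exp(-cfg$ld_decay * diff(pos))
        for (j in 2L:m) {
          z[, j] <- ar[j - 1L] * z[, j - 1L] +
            sqrt(1 - ar[j - 1L]^2) * z[, j]
        }
      }
      founders <- matrix(0L, cfg$n_founders, m)
      founders[sweep(z, 2L, stats::qnorm(freq), "<=")] <- 1L
      gam <- matrix(0L, nrow = 2L * n, ncol = m)
      f <- sample.int(cfg$n_founders, 2L * n, replace = TRUE)
      gam[, 1L] <- founders[f, 1L]
      if (m > 1L) {
        p_switch <- 1 - exp(-cfg$ld_decay * diff(pos))
        for (j in 2L:m) {
          sw <- stats::runif(2L * n) < p_switch[j - 1L]
          if (any(sw)) {
            f[sw] <- sample.int(cfg$n_founders, sum(sw), replace = TRUE)
          }
          gam[, j] <- founders[f, j]
        }
      }
      hap_list1[[cc]] <- gam[seq_len(n), , drop = FALSE]
      hap_list2[[cc]] <- gam[n + seq_len(n), , drop = FALSE]
      mk[[cc]] <- tibble::tibble(
        marker_id = paste0("chr", cc, "_", pos),
        chrom = paste0("chr", cc),
        pos = pos
      )
    }
    phased_genotypes(do.call(cbind, hap_list1), do.call(cbind, hap_list2),
                     dplyr::bind_rows(mk),
                     ids = sprintf("ind_%04d", seq_len(n)))
  })
}

#' Simulate a nested gene annotation
#'
#' Places non-overlapping genes per chromosome, nests exons within genes,
#' and partitions every exon into CDS and UTR segments (terminal exons get
#' the UTR ends), so the class-nesting invariants of real annotations hold
#' by construction: CDS and UTR tile each exon, exons lie within genes.
#'
#' @param cfg A [sim_config()].
#' @return A features tibble (`feature_id`, `class`, `chrom`, `start`,
#'   `end`) with classes gene/exon/CDS/UTR.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    rows <- list()
    for (cc in seq_len(cfg$n_chromosomes)) {
      chrom <- paste0("chr", cc)
      ng <- cfg$n_genes
      glen <- round(stats::runif(ng, cfg$gene_length[1], cfg$gene_length[2]))
      if (sum(glen) + ng + 1 > cfg$chrom_length) {
        stop("infeasible packing: genes exceed chromosome length", call. = FALSE)
      }
      free <- cfg$chrom_length - sum(glen)
      w <- stats::runif(ng + 1)
      gaps <- floor(w / sum(w) * (free - (ng + 1))) + 1L
      gstart <- integer(ng)
      at <- 0L
      for (i in seq_len(ng)) {
        at <- at + gaps[i]
        gstart[i] <- at + 1L
        at <- at + glen[i]
      }
      for (i in seq_len(ng)) {
        gid <- paste0("gene:", chrom, ":g", i)
        gs <- gstart[i]; ge <- gstart[i] + glen[i] - 1L
        rows[[length(rows) + 1L]] <- tibble::tibble(
          feature_id = gid, class = "gene", chrom = chrom,
          start = gs, end = ge
        )
        k <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1L)
        elen <- round(stats::runif(k, cfg$exon_length[1], cfg$exon_length[2]))
        if (sum(elen) > 0.8 * glen[i]) {
          elen <- pmax(60L, floor(elen * 0.8 * glen[i] / sum(elen)))
        }
        efree <- glen[i] - sum(elen)
        ew <- stats::runif(k + 1)
        egap <- floor(ew / sum(ew) * efree)
        eat <- gs - 1L
        for (e in seq_len(k)) {
          eat <- eat + egap[e]
          es <- eat + 1L; ee <- eat + elen[e]
          eat <- ee
          eid <- paste0("exon:", chrom, ":g", i, "e", e)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            feature_id = eid, class = "exon", chrom = chrom,
            start = es, end = ee
          )
          # CDS/UTR partition: UTR caps on the terminal exons
          len <- ee - es + 1L
          utr_head <- if (e == 1L) max(1L, floor(len * stats::runif(1, 0.1, 0.3))) else 0L
          utr_tail <- if (e == k) max(1L, floor(len * stats::runif(1, 0.1, 0.3))) else 0L
          if (utr_head + utr_tail >= len) {  # tiny exon: all UTR
            rows[[length(rows) + 1L]] <- tibble::tibble(
              feature_id = paste0("utr:", chrom, ":g", i, "e", e),
              class = "UTR", chrom = chrom, start = es, end = ee
            )
          } else {
            if (utr_head > 0L) {
              rows[[length(rows) + 1L]] <- tibble::tibble(
                feature_id = paste0("utr5:", chrom, ":g", i, "e", e),
                class = "UTR", chrom = chrom,
                start = es, end = es + utr_head - 1L
              )
            }
            rows[[length(rows) + 1L]] <- tibble::tibble(
              feature_id = paste0("cds:", chrom, ":g", i, "e", e),
              class = "CDS", chrom = chrom,
              start = es + utr_head, end = ee - utr_tail
            )
            if (utr_tail > 0L) {
              rows[[length(rows) + 1L]] <- tibble::tibble(
                feature_id = paste0("utr3:", chrom, ":g", i, "e", e),
                class = "UTR", chrom = chrom,
                start = ee - utr_tail + 1L, end = ee
              )
            }
          }
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate phenotypes under a configurable genetic architecture
#'
#' Genetic values are built from planted QTL (additive SNP effects,
#' effects attached to the distinct haplotype alleles of marker windows, or
#' effects attached to unordered genotype combinations of locus pairs),
#' centred and scaled so that `var(g) / (var(g) + var(e))` hits the target
#' heritability; sex, year and two covariates are added on top. The truth
#' component records everything needed to recompute the phenotypes.
#'
#' @param g A [phased_genotypes] object (complete; typically QC-passed).
#' @param features Annotation tibble (used for gene-biased QTL placement).
#' @param cfg A [sim_config()].
#' @return A list with `phenotypes` (tibble: `id`, `trait`, `sex`, `year`,
#'   `entry_weight`, `fattening_days`) and `truth` (list: `genetic_value`,
#'   `residual`, `fixed_part`, `realized_h2`, `architecture`, `qtl`).
#' @export
simulate_phenotypes <- function(g, features, cfg) {
  stopifnot(inherits(g, "phased_genotypes"), inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 2L, {
    n <- length(g$ids)
    mk <- g$markers
    gene_gr <- features_to_granges(features[features$class == "gene", ])
    mpos <- GenomicRanges::GRanges(mk$chrom, IRanges::IRanges(mk$pos, width = 1L))
    in_gene <- GenomicRanges::countOverlaps(mpos, gene_gr) > 0
    maf_ok <- !is.na(mk$maf) & mk$maf > 0
    arch <- cfg$architecture
    pick_loci <- function(n_pick, window = 1L) {
      # window heads must leave room on the same chromosome
      chrom_ok <- rep(TRUE, nrow(mk))
      if (window > 1L) {
        idx_by_chrom <- split(seq_len(nrow(mk)), mk$chrom)
        for (ii in idx_by_chrom) {
          if (length(ii) >= window) {
            chrom_ok[ii[(length(ii) - window + 2L):length(ii)]] <- FALSE
          } else {
            chrom_ok[ii] <- FALSE
          }
        }
      }
      pool_in <- which(in_gene & maf_ok & chrom_ok)
      pool_out <- which(!in_gene & maf_ok & chrom_ok)
      k_in <- round(n_pick * cfg$qtl_class_bias)
      k_out <- n_pick - k_in
      if (length(pool_in) < k_in || length(pool_out) < k_out) {
        stop("not enough eligible markers for the requested QTL placement",
             call. = FALSE)
      }
      sort(c(sample(pool_in, k_in), sample(pool_out, k_out)))
    }
    qtl_truth <- list()
    gval_add <- gval_hap <- gval_epi <- NULL
    if (arch %in% c("snp_additive", "mixed")) {
      loci <- pick_loci(cfg$n_qtl)
      beta <- stats::rnorm(length(loci))
      M <- dosage(g)[, loci, drop = FALSE]
      gval_add <- drop(M %*% beta)
      qtl_truth$additive <- tibble::tibble(
        marker = loci, marker_id = mk$marker_id[loci], effect = beta,
        in_gene = in_gene[loci]
      )
    }
    if (arch %in% c("haplotype_qtl", "mixed")) {
      wmax <- cfg$qtl_window[2]
      heads <- pick_loci(cfg$n_qtl, window = wmax)
      H <- rbind(g$hap1, g$hap2)
      gval_hap <- numeric(n)
      qtl_truth$haplotype <- vector("list", length(heads))
      for (i in seq_along(heads)) {
        w <- sample(seq(cfg$qtl_window[1], cfg$qtl_window[2]), 1L)
        idx <- heads[i]:(heads[i] + w - 1L)
        strings <- apply(H[, idx, drop = FALSE], 1L, paste, collapse = "")
        catalog <- sort(unique(strings))
        eff <- stats::rnorm(length(catalog))
        a <- match(strings, catalog)
        gval_hap <- gval_hap + eff[a[seq_len(n)]] + eff[a[n + seq_len(n)]]
        qtl_truth$haplotype[[i]] <- list(
          markers = idx, alleles = catalog, effects = eff,
          allele1 = a[seq_len(n)], allele2 = a[n + seq_len(n)],
          in_gene = in_gene[heads[i]]
        )
      }
    }
    if (arch == "epistatic") {
      # effects attach to unordered pairs of window genotype configurations,
      # the state a haploblock-pair epistasis kernel measures
      n_pairs <- max(1L, cfg$n_qtl %/% 2L)
      w <- 2L   # two-SNP windows keep joint configurations shareable
      heads <- pick_loci(2L * n_pairs, window = w)
      heads <- matrix(sample(heads), ncol = 2L)
      H <- rbind(g$hap1, g$hap2)
      config_of <- function(head) {
        idx <- head:(head + w - 1L)
        s <- apply(H[, idx, drop = FALSE], 1L, paste, collapse = "")
        paste(pmin(s[seq_len(n)], s[n + seq_len(n)]),
              pmax(s[seq_len(n)], s[n + seq_len(n)]), sep = "|")
      }
      gval_epi <- numeric(n)
      qtl_truth$epistatic <- vector("list", n_pairs)
      for (i in seq_len(n_pairs)) {
        joint <- paste(config_of(heads[i, 1L]), config_of(heads[i, 2L]),
                       sep = "~")
        states <- sort(unique(joint))
        eff <- stats::rnorm(length(states))
        gval_epi <- gval_epi + eff[match(joint, states)]
        qtl_truth$epistatic[[i]] <- list(heads = heads[i, ], window = w,
                                         states = states, effects = eff)
      }
    }
    parts <- list(gval_add, gval_hap, gval_epi)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (arch == "mixed") {
      parts <- lapply(parts, function(x) {
        if (stats::sd(x) == 0) x else (x - mean(x)) / stats::sd(x)
      })
      gval <- Reduce(`+`, parts) / sqrt(length(parts))
    } else {
      gval <- parts[[1]]
    }
    if (stats::sd(gval) == 0) {
      stop("zero genetic variance after QTL placement", call. = FALSE)
    }
    gval <- (gval - mean(gval)) / stats::sd(gval) * sqrt(cfg$h2_target)
    resid <- stats::rnorm(n, sd = sqrt(1 - cfg$h2_target))
    realized_h2 <- stats::var(gval) / (stats::var(gval) + stats::var(resid))
    sex <- factor(sample(paste0("sex", seq_len(cfg$sex_levels)), n, TRUE))
    year <- factor(sample(2008L + seq_len(cfg$year_levels) - 1L, n, TRUE))
    entry_weight <- stats::rnorm(n, 250, 25)
    fattening_days <- round(stats::rnorm(n, 240, 20))
    sex_eff <- stats::rnorm(cfg$sex_levels, 0, cfg$fixed_sd)
    year_eff <- stats::rnorm(cfg$year_levels, 0, cfg$fixed_sd)
    fixed_part <- sex_eff[as.integer(sex)] + year_eff[as.integer(year)] +
      cfg$fixed_sd * as.numeric(scale(entry_weight)) +
      cfg$fixed_sd * as.numeric(scale(fattening_days))
    trait <- 10 + fixed_part + gval + resid
    list(
      phenotypes = tibble::tibble(
        id = g$ids, trait = trait, sex = sex, year = year,
        entry_weight = entry_weight, fattening_days = fattening_days
      ),
      truth = list(
        genetic_value = gval, residual = resid, fixed_part = fixed_part,
        realized_h2 = realized_h2, architecture = arch, qtl = qtl_truth
      )
    )
  })
}

#' Simulate a complete dataset
#'
#' Runs [simulate_haplotypes()], [simulate_annotation()] and
#' [simulate_phenotypes()] under one configuration; optionally writes the
#' phased VCF, GFF3 and phenotype/truth tables. Byte-identical outputs for
#' identical configurations.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory for `genotypes.vcf`,
#'   `annotation.gff3`, `phenotypes.tsv`, `truth.tsv`.
#' @return List with `genotypes`, `features`, `phenotypes`, `truth`,
#'   `chrom_lengths`, `config`.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  g <- simulate_haplotypes(cfg)
  features <- simulate_annotation(cfg)
  ph <- simulate_phenotypes(g, features, cfg)
  cl <- sim_chrom_lengths(cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_phased_vcf(g, file.path(dir, "genotypes.vcf"), cl)
    write_gff3(features, file.path(dir, "annotation.gff3"), cl)
    write_phenotypes(ph$phenotypes, file.path(dir, "phenotypes.tsv"))
    utils::write.table(
      data.frame(id = g$ids, genetic_value = ph$truth$genetic_value,
                 residual = ph$truth$residual),
      file.path(dir, "truth.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  list(genotypes = g, features = features, phenotypes = ph$phenotypes,
       truth = ph$truth, chrom_lengths = cl, config = cfg)
}

#' Write features as GFF3
#'
#' @param features A features tibble (classes gene/exon/CDS/UTR; IGR rows
#'   are skipped since they are derived, not annotated).
#' @param path Output path.
#' @param chrom_lengths Optional named lengths for `##sequence-region`
#'   directives.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, chrom_lengths = NULL) {
  features <- tibble::as_tibble(features)
  features <- features[features$class != "IGR", ]
  header <- c("##gff-version 3",
              if (!is.null(chrom_lengths)) {
                paste("##sequence-region", names(chrom_lengths), 1L,
                      as.integer(chrom_lengths))
              })
  body <- paste(features$chrom, "haplogp_sim", features$class,
                features$start, features$end, ".", "+", ".",
                paste0("ID=", features$feature_id),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
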