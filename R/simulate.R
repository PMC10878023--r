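# Seeded synthetic-data generation with planted truth: genome with N
# blocks, planted off-target sites per category, joint clone callsets with
# planted clone-unique INDELs / differential genotypes / AF drift, coverage
# tracks with planted fractional-depth CNVs, CNV/SV call lists, and
# methylation metadata + beta values with a planted strain effect.
# Every generator is a pure function of its seed.

#' Generate a random genome with N blocks
#'
#' I.i.d. uniform A/C/G/T with N blocks overwritten at the given positions.
#'
#' @param seed Integer seed.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_blocks Optional data frame `chrom`, `start` (0-based), `width`
#'   of N blocks.
#' @return A `genome_sequence`.
#' @export
make_genome <- function(seed, chrom_lengths = c(chr1 = 300000L,
                                                chr2 = 300000L,
                                                chr3 = 300000L),
                        n_blocks = NULL) {
  stopifnot(all(chrom_lengths > 0L), !is.null(names(chrom_lengths)))
  with_seed(seed, {
    seqs <- vapply(chrom_lengths, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
    if (!is.null(n_blocks)) {
      for (i in seq_len(nrow(n_blocks))) {
        ch <- n_blocks$chrom[i]
        s0 <- n_blocks$start[i]
        w <- n_blocks$width[i]
        stopifnot(ch %in% names(seqs), s0 >= 0L,
                  s0 + w <= chrom_lengths[[ch]])
        substr(seqs[[ch]], s0 + 1L, s0 + w) <-
          paste(rep("N", w), collapse = "")
      }
    }
    genome_sequence(seqs)
  })
}

random_pam <- function(pattern, n) {
  pat <- strsplit(pattern, "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(vapply(pat, function(code) {
      ch <- iupac_chars(code)
      if (length(ch) == 1L) ch else sample(ch, 1L)
    }, character(1)), collapse = "")
  }, character(1))
}

# derive a site sequence from the guide: exactly mm substitutions at random
# protospacer positions, plus the requested interior bulge
derived_site_seq <- function(protospacer, mm, bulge) {
  g <- nchar(protospacer)
  bases <- strsplit(protospacer, "")[[1]]
  if (bulge == "rna") {
    d <- sample(2:(g - 1L), 1L)          # guide base left unpaired
    bases <- bases[-d]
  } else if (bulge == "dna") {
    t <- sample(2:g, 1L)                 # extra genomic base, interior
    bases <- append(bases, sample(c("A", "C", "G", "T"), 1L), after = t - 1L)
  }
  if (mm > 0L) {
    idx <- sample(length(bases), mm)
    for (i in idx) {
      bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
    }
  }
  paste(bases, collapse = "")
}

#' Plant off-target sites of known category into a genome
#'
#' For each requested (mismatches, PAM, bulge) category, writes the
#' requested number of guide-derived sequences (exactly `mismatches`
#' substitutions at random positions, a PAM sampled from the category's
#' pattern, the stated interior bulge, random strand) at random
#' well-separated positions. The construction is verified by scanning the
#' mutated genome: a planted site whose recovered category differs from the
#' request (e.g. a substitution draw that is explicable with fewer
#' mismatches through a bulge) is redrawn. All remaining hits of the
#' verification scan are recorded as background.
#'
#' @param genome A `genome_sequence`.
#' @param guide A [guide_spec()] (its `max_mismatches`/`bulge_size` bound
#'   the verification scan together with the planted categories).
#' @param category_counts Data frame `mismatches`, `pam` (concrete-ish
#'   IUPAC pattern to sample from, e.g. "NGG"/"NAG"), `bulge`
#'   ("none"/"rna"/"dna"), `count`.
#' @param seed Integer seed.
#' @param flank Half-width in bp of the "off-target region" recorded around
#'   each planted footprint (default 100; planted INDEL enrichment uses
#'   these regions).
#' @param min_gap Minimum bp between planted footprints (default 300).
#' @return List: `genome` (mutated), `truth` (planted sites with footprint
#'   and region intervals), `background` (unplanned hits of the scan),
#'   `guide`.
#' @export
plant_offtargets <- function(genome, guide, category_counts, seed,
                             flank = 100L, min_gap = 300L) {
  check_genome(genome)
  stopifnot(all(c("mismatches", "pam", "bulge", "count") %in%
                  names(category_counts)))
  lens <- chrom_lengths(genome)
  g <- nchar(guide$protospacer)
  p <- nchar(guide$pam_pattern)
  # every planted PAM class must be recoverable under the guide's pattern
  guide_pam <- strsplit(guide$pam_pattern, "")[[1]]
  for (cls in unique(category_counts$pam)) {
    cls_pam <- strsplit(cls, "")[[1]]
    stopifnot(length(cls_pam) == p)
    covered <- all(vapply(seq_len(p), function(j) {
      all(iupac_chars(cls_pam[j]) %in% iupac_chars(guide_pam[j]))
    }, logical(1)))
    if (!covered) {
      stop("planted PAM class ", cls, " is not covered by the search ",
           "pattern ", guide$pam_pattern, call. = FALSE)
    }
  }
  scan_guide <- guide_spec(guide$protospacer, guide$pam_pattern,
                           max_mismatches = max(category_counts$mismatches,
                                                guide$max_mismatches),
                           bulge_size = max(
                             guide$bulge_size,
                             as.integer(any(category_counts$bulge != "none"))))

  req <- category_counts[rep(seq_len(nrow(category_counts)),
                             category_counts$count), , drop = FALSE]
  n_req <- nrow(req)
  with_seed(seed, {
    seqs <- as.list(unclass(genome))
    placed <- data.frame(chrom = character(), start = integer(),
                         end = integer())
    truth <- vector("list", n_req)
    # local pre-verification: embed the candidate content in its real
    # flanks and require the scanner to report exactly the planted
    # category at the planted footprint (a high-mismatch substitution
    # draw is often explicable with fewer mismatches through a bulge)
    local_ok <- function(window, plus_seq, flen, strand, mm, bulge) {
      substr(window, min_gap + 1L, min_gap + flen) <- plus_seq
      hits <- find_offtarget_sites(genome_sequence(c(w = window)),
                                   scan_guide)
      any(hits$start == min_gap & hits$end == min_gap + flen &
            hits$strand == strand & hits$mismatches == mm &
            hits$bulge == bulge)
    }
    draw_content <- function(mm, bulge, pam_class, strand, window, flen) {
      for (try in seq_len(300L)) {
        site <- derived_site_seq(guide$protospacer, mm, bulge)
        plus_seq <- paste0(site, random_pam(pam_class, 1L))
        if (strand == "-") {
          plus_seq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(plus_seq)))
        }
        if (local_ok(window, plus_seq, flen, strand, mm, bulge)) {
          return(plus_seq)
        }
      }
      NULL
    }
    for (i in seq_len(n_req)) {
      mm <- req$mismatches[i]
      bulge <- req$bulge[i]
      flen <- g + p + c(none = 0L, rna = -1L, dna = 1L)[[bulge]]
      ok <- FALSE
      for (try in seq_len(200L)) {
        strand <- sample(c("+", "-"), 1L)
        chrom <- sample(names(lens), 1L, prob = lens)
        lo <- min_gap; hi <- lens[[chrom]] - flen - min_gap
        if (hi <= lo) next
        s0 <- sample.int(hi - lo, 1L) + lo           # 0-based start
        window <- substr(seqs[[chrom]], s0 + 1L - min_gap,
                         s0 + flen + min_gap)
        if (grepl("N", window, fixed = TRUE)) next
        clash <- placed$chrom == chrom &
          placed$start < s0 + flen + min_gap &
          s0 - min_gap < placed$end
        if (any(clash)) next
        plus_seq <- draw_content(mm, bulge, req$pam[i], strand, window,
                                 flen)
        if (is.null(plus_seq)) next
        substr(seqs[[chrom]], s0 + 1L, s0 + flen) <- plus_seq
        placed <- rbind(placed, data.frame(chrom = chrom, start = s0,
                                           end = s0 + flen))
        truth[[i]] <- data.frame(
          chrom = chrom, start = s0, end = s0 + flen, strand = strand,
          mismatches = mm, pam_class = req$pam[i], bulge = bulge,
          region_start = max(s0 - flank, 0L),
          region_end = min(s0 + flen + flank, lens[[chrom]]),
          stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place planted site ", i,
                    " (genome too small or crowded)", call. = FALSE)
    }
    truth <- do.call(rbind, truth)
    mutated <- genome_sequence(unlist(seqs))

    # verification: every planted site must be recovered with its planted
    # category; redraw the sequence content of any that are not
    truth_key <- paste(truth$chrom, truth$start, truth$end, truth$strand)
    hits <- NULL
    for (round in seq_len(10L)) {
      hits <- find_offtarget_sites(mutated, scan_guide)
      hit_key <- paste(hits$chrom, hits$start, hits$end, hits$strand)
      m <- match(truth_key, hit_key)
      bad <- which(is.na(m) | hits$mismatches[m] != truth$mismatches |
                     hits$bulge[m] != truth$bulge)
      if (length(bad) == 0L) break
      if (round == 10L) {
        stop("planted off-target verification failed after redraws",
             call. = FALSE)
      }
      seqs <- as.list(unclass(mutated))
      for (i in bad) {
        flen <- truth$end[i] - truth$start[i]
        window <- substr(seqs[[truth$chrom[i]]],
                         truth$start[i] + 1L - min_gap,
                         truth$end[i] + min_gap)
        plus_seq <- draw_content(truth$mismatches[i], truth$bulge[i],
                                 truth$pam_class[i], truth$strand[i],
                                 window, flen)
        if (is.null(plus_seq)) {
          stop("planted off-target verification failed after redraws",
               call. = FALSE)
        }
        substr(seqs[[truth$chrom[i]]], truth$start[i] + 1L,
               truth$end[i]) <- plus_seq
      }
      mutated <- genome_sequence(unlist(seqs))
    }
    hit_key <- paste(hits$chrom, hits$start, hits$end, hits$strand)
    background <- hits[!hit_key %in% truth_key, , drop = FALSE]
    rownames(background) <- NULL
    list(genome = mutated, truth = truth, background = background,
         guide = guide)
  })
}

#' Default simulation parameters
#'
#' The desk-scale study conditions emulated by [simulate_dataset()]: a
#' 3 x 1 Mb genome with two N blocks; ~120 planted off-target sites across
#' mismatch/PAM/bulge categories; two clones ("HR1ex" edited, "WT" control)
#' sharing most calls, each with 600 unique INDELs, the edited clone's
#' placed with 3x density inside off-target regions; 100 differential
#' biallelic genotypes and 30 drifted allele frequencies; ~30x coverage
#' with a 5-bin 0.45x deletion, a 1-bin 1.3x gain and two single-bin depth
#' artifacts in the edited clone; CNV/SV call lists; and a 7-tissue
#' methylation cohort with a +0.15 beta strain effect at 2 probes in 2
#' tissues.
#'
#' @param ... Overrides for individual entries.
#' @return Named list of parameters.
#' @export
default_sim_params <- function(...) {
  params <- list(
    chrom_lengths = c(chr1 = 1000000L, chr2 = 1000000L, chr3 = 1000000L),
    n_blocks = data.frame(chrom = c("chr1", "chr3"),
                          start = c(400000L, 700000L),
                          width = c(200L, 80L), stringsAsFactors = FALSE),
    guide_length = 20L,
    pam_search = "NRG",
    category_counts = data.frame(
      mismatches = c(0L, 2L, 4L, 4L, 5L, 6L, 6L, 6L, 6L, 7L, 7L),
      pam = c("NGG", "NGG", "NGG", "NAG", "NGG", "NGG", "NAG", "NGG",
              "NGG", "NGG", "NAG"),
      bulge = c("none", "none", "none", "none", "none", "none", "none",
                "rna", "dna", "none", "none"),
      count = c(1L, 8L, 30L, 20L, 40L, 55L, 40L, 20L, 20L, 55L, 30L),
      stringsAsFactors = FALSE),
    region_flank = 100L,
    clone_a = "HR1ex", clone_b = "WT",
    n_shared_snv = 1200L, n_shared_indel = 200L,
    n_unique_indel_a = 600L, n_unique_indel_b = 600L,
    enrichment_factor = 3.0,
    n_diff_geno = 100L, n_drift = 30L,
    drift_delta_range = c(0.55, 0.95),
    fail_frac = 0.1,
    mean_depth = 30,
    alt_model = "exact",
    coverage_model = "poisson",
    cnvs_a = data.frame(
      chrom = c("chr2", "chr3"), start = c(0L, 50000L),
      end = c(250000L, 100000L), cnv_type = c("deletion", "duplication"),
      mult = c(0.45, 1.3), stringsAsFactors = FALSE),
    cnvs_shared = data.frame(
      chrom = c("chr1", "chr3"), start = c(600000L, 800000L),
      end = c(650000L, 850000L), cnv_type = c("deletion", "duplication"),
      mult = c(0.5, 1.4), stringsAsFactors = FALSE),
    artifacts_a = data.frame(
      chrom = c("chr1", "chr3"), start = c(100000L, 200000L),
      end = c(150000L, 250000L), mult = c(0.45, 0.45),
      stringsAsFactors = FALSE),
    n_sv_unique = 4L, n_sv_low_support = 2L, n_sv_shared = 2L,
    tissues = c("liver", "kidney", "lung", "spleen", "heart", "brain",
                "blood"),
    n_per_stratum = 8L, n_probes = 12L, n_effect_probes = 2L,
    n_effect_tissues = 2L, delta_beta = 0.15, noise_sd = 0.04,
    age_range = c(0L, 365L)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  # wholesale replacement (modifyList would merge into data frame entries)
  for (nm in names(overrides)) params[[nm]] <- overrides[[nm]]
  params
}

# sample n distinct variant anchor positions with a minimum separation,
# avoiding Ns; optionally biased into regions by an enrichment factor
sample_variant_positions <- function(genome, n, width = 12L, min_sep = 15L,
                                     occupied = NULL, regions = NULL,
                                     factor = 1.0) {
  lens <- chrom_lengths(genome)
  chroms <- names(lens)
  occ <- if (is.null(occupied)) {
    data.frame(chrom = character(), pos = integer())
  } else occupied
  region_mass <- if (!is.null(regions) && nrow(regions)) {
    sum(regions$end - regions$start)
  } else 0
  total <- sum(lens)
  p_in <- if (region_mass > 0) {
    factor * region_mass / (total - region_mass + factor * region_mass)
  } else 0
  out_chrom <- character(n)
  out_pos <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      inside <- region_mass > 0 && runif(1) < p_in
      if (inside) {
        w <- regions$end - regions$start
        r <- sample.int(nrow(regions), 1L, prob = w)
        lo <- regions$start[r] + 1L
        hi <- regions$end[r] - width
        if (hi < lo) next
        chrom <- regions$chrom[r]
        pos <- sample.int(hi - lo + 1L, 1L) + lo - 1L
      } else {
        chrom <- sample(chroms, 1L, prob = lens)
        hi <- lens[[chrom]] - width - 1L
        pos <- sample.int(hi, 1L) + 1L
        if (region_mass > 0) {
          inr <- regions$chrom == chrom & regions$start < pos + width &
            pos - 1L < regions$end
          if (any(inr)) next                 # outside draws stay outside
        }
      }
      if (grepl("N", substr(unclass(genome)[[chrom]], pos, pos + width),
                fixed = TRUE)) next
      near <- occ$chrom == chrom & abs(occ$pos - pos) < min_sep
      if (any(near)) next
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place variant ", i, call. = FALSE)
    out_chrom[i] <- chrom
    out_pos[i] <- pos
    occ <- rbind(occ, data.frame(chrom = chrom, pos = pos))
  }
  list(chrom = out_chrom, pos = out_pos,
       occupied = occ, in_region = if (region_mass > 0) {
         vapply(seq_len(n), function(i) {
           any(regions$chrom == out_chrom[i] &
                 regions$start < out_pos[i] + width &
                 out_pos[i] - 1L < regions$end)
         }, logical(1))
       } else rep(FALSE, n))
}

draw_pass_stats <- function(n) {
  data.frame(FS = runif(n, 0, 30), QD = runif(n, 5, 30),
             MQ = runif(n, 50, 60), SOR = runif(n, 0.3, 2.5),
             MQRankSum = runif(n, -3, 3), ReadPosRankSum = runif(n, -3, 3),
             qual = runif(n, 100, 2000))
}

plant_stat_failures <- function(stats, vtype, fail) {
  snv_stats <- c("QD", "qual", "SOR", "FS", "MQ", "MQRankSum",
                 "ReadPosRankSum")
  indel_stats <- c("FS", "ReadPosRankSum", "qual", "QD")
  for (i in which(fail)) {
    if (vtype[i] == "SNV") {
      s <- sample(snv_stats, 1L)
      stats[i, s] <- switch(s,
        QD = runif(1, 0, 1.9), qual = runif(1, 1, 29),
        SOR = runif(1, 3.1, 6), FS = runif(1, 61, 150),
        MQ = runif(1, 10, 39), MQRankSum = runif(1, -20, -13),
        ReadPosRankSum = runif(1, -12, -8.5))
    } else {
      s <- sample(indel_stats, 1L)
      stats[i, s] <- switch(s,
        FS = runif(1, 201, 400), ReadPosRankSum = runif(1, -30, -20.5),
        qual = runif(1, 1, 29), QD = runif(1, 0, 1.9))
    }
  }
  stats
}

random_indel_alleles <- function(genome, chrom, pos) {
  del <- runif(1) < 0.5
  k <- sample.int(8L, 1L)
  anchor <- substr(unclass(genome)[[chrom]], pos, pos)
  if (del) {
    ref <- substr(unclass(genome)[[chrom]], pos, pos + k)
    list(ref = ref, alt = anchor)
  } else {
    ins <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                 collapse = "")
    list(ref = anchor, alt = paste0(anchor, ins))
  }
}

alt_from_af <- function(depth, af, model) {
  if (model == "exact") {
    as.integer(round(af * depth))
  } else {
    rbinom(length(depth), depth, af)
  }
}

#' Simulate joint clone callsets with planted truth
#'
#' Generates shared variants, clone-unique INDELs (the edited clone's with
#' `enrichment_factor`-fold density inside `regions`), differential
#' biallelic genotypes and allele-frequency drift sites, with site
#' statistics drawn inside the hard-filter pass ranges except a `fail_frac`
#' fraction of shared records planted to violate one threshold each.
#'
#' @param genome A `genome_sequence`.
#' @param regions Off-target region intervals (0-based half-open) used for
#'   enriched placement; may be `NULL`.
#' @param seed Integer seed.
#' @param params [default_sim_params()] list (only the variant-model
#'   entries are used).
#' @return List: `sites` (site table), `samples` (named list of per-sample
#'   gt/depth/alt_reads data frames, clone A first), `truth`.
#' @export
simulate_clone_callsets <- function(genome, regions, seed,
                                    params = default_sim_params()) {
  p <- params
  with_seed(seed, {
    occ <- NULL
    draw <- function(n, regions = NULL, factor = 1.0) {
      res <- sample_variant_positions(genome, n, occupied = occ,
                                      regions = regions, factor = factor)
      occ <<- res$occupied
      res
    }
    n_sh_s <- p$n_shared_snv; n_sh_i <- p$n_shared_indel
    sh_s <- draw(n_sh_s)
    sh_i <- draw(n_sh_i)
    un_a <- draw(p$n_unique_indel_a, regions = regions,
                 factor = p$enrichment_factor)
    un_b <- draw(p$n_unique_indel_b, regions = regions, factor = 1.0)
    df_g <- draw(p$n_diff_geno)
    dr <- draw(p$n_drift)

    base_at <- function(chrom, pos) {
      substr(unclass(genome)[[chrom]], pos, pos)
    }
    other_base <- function(b) {
      vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
             character(1))
    }
    mk_snv <- function(loc, role) {
      if (length(loc$pos) == 0L) return(NULL)
      ref <- mapply(base_at, loc$chrom, loc$pos)
      data.frame(chrom = loc$chrom, pos = loc$pos, ref = unname(ref),
                 alt = unname(other_base(ref)), vtype = "SNV", role = role,
                 in_region = loc$in_region, stringsAsFactors = FALSE)
    }
    mk_indel <- function(loc, role) {
      if (length(loc$pos) == 0L) return(NULL)
      al <- lapply(seq_along(loc$pos), function(i) {
        random_indel_alleles(genome, loc$chrom[i], loc$pos[i])
      })
      data.frame(chrom = loc$chrom, pos = loc$pos,
                 ref = vapply(al, `[[`, character(1), "ref"),
                 alt = vapply(al, `[[`, character(1), "alt"),
                 vtype = "INDEL", role = role, in_region = loc$in_region,
                 stringsAsFactors = FALSE)
    }
    sites <- rbind(mk_snv(sh_s, "shared_snv"), mk_indel(sh_i, "shared_indel"),
                   mk_indel(un_a, "unique_a"), mk_indel(un_b, "unique_b"),
                   mk_snv(df_g, "diff_geno"), mk_snv(dr, "drift"))
    n <- nrow(sites)
    stats <- draw_pass_stats(n)
    shared <- sites$role %in% c("shared_snv", "shared_indel")
    fail <- shared & runif(n) < p$fail_frac
    stats <- plant_stat_failures(stats, sites$vtype, fail)
    sites <- cbind(sites, stats)
    sites$planted_fail <- fail

    d <- function(n) pmax(rpois(n, p$mean_depth), 1L)
    gt_a <- gt_b <- character(n)
    dp_a <- dp_b <- integer(n)
    af_a <- af_b <- numeric(n)
    # shared variants: identical genotype and AF in both clones
    sh <- which(shared)
    hom <- runif(length(sh)) < 0.4
    gt_a[sh] <- gt_b[sh] <- ifelse(hom, "1/1", "0/1")
    af_a[sh] <- af_b[sh] <- ifelse(hom, 1, 0.5)
    # clone-unique heterozygous INDELs; the other clone is clean 0/0
    ua <- which(sites$role == "unique_a")
    gt_a[ua] <- "0/1"; af_a[ua] <- 0.5; gt_b[ua] <- "0/0"; af_b[ua] <- 0
    ub <- which(sites$role == "unique_b")
    gt_b[ub] <- "0/1"; af_b[ub] <- 0.5; gt_a[ub] <- "0/0"; af_a[ub] <- 0
    # differential genotypes at guaranteed depth
    dg <- which(sites$role == "diff_geno")
    pat <- sample(c("het_hom", "hom_het", "het_ref", "ref_het"),
                  length(dg), replace = TRUE)
    gt_a[dg] <- c(het_hom = "0/1", hom_het = "1/1", het_ref = "0/1",
                  ref_het = "0/0")[pat]
    gt_b[dg] <- c(het_hom = "1/1", hom_het = "0/1", het_ref = "0/0",
                  ref_het = "0/1")[pat]
    af_of_gt <- c("0/0" = 0, "0/1" = 0.5, "1/1" = 1)
    af_a[dg] <- af_of_gt[gt_a[dg]]
    af_b[dg] <- af_of_gt[gt_b[dg]]
    # AF drift with unchanged het genotype calls
    dri <- which(sites$role == "drift")
    delta <- runif(length(dri), p$drift_delta_range[1],
                   p$drift_delta_range[2])
    lo <- runif(length(dri), 0.01, 1 - delta - 0.01)
    swap <- runif(length(dri)) < 0.5
    af_a[dri] <- ifelse(swap, lo + delta, lo)
    af_b[dri] <- ifelse(swap, lo, lo + delta)
    gt_a[dri] <- gt_b[dri] <- "0/1"

    dp_a <- d(n); dp_b <- d(n)
    # even depths keep het fractions at exactly 0.5, so genotype switches
    # sit on (not beyond) the drift screen's 0.5 boundary
    dp_a[dg] <- 2L * sample(10:40, length(dg), replace = TRUE)
    dp_b[dg] <- 2L * sample(10:40, length(dg), replace = TRUE)
    dp_a[dri] <- pmax(rpois(length(dri), 40), 21L)
    dp_b[dri] <- pmax(rpois(length(dri), 40), 21L)
    ar_a <- alt_from_af(dp_a, af_a, p$alt_model)
    ar_b <- alt_from_af(dp_b, af_b, p$alt_model)

    samples <- setNames(list(
      data.frame(gt = gt_a, depth = dp_a, alt_reads = ar_a),
      data.frame(gt = gt_b, depth = dp_b, alt_reads = ar_b)),
      c(p$clone_a, p$clone_b))
    truth <- list(
      n_planted_fail = sum(fail),
      n_unique_indel_a = length(ua), n_unique_indel_b = length(ub),
      n_unique_a_in_region = sum(sites$in_region[ua]),
      n_diff_geno = length(dg), n_drift = length(dri),
      drift = data.frame(chrom = sites$chrom[dri], pos = sites$pos[dri],
                         af_a = af_a[dri], af_b = af_b[dri],
                         stringsAsFactors = FALSE),
      unique_a = sites[ua, c("chrom", "pos", "ref", "alt", "in_region")],
      unique_b = sites[ub, c("chrom", "pos", "ref", "alt", "in_region")])
    list(sites = sites, samples = samples, truth = truth)
  })
}

#' Build in-memory callsets from a simulation
#'
#' @param sim Output of [simulate_clone_callsets()].
#' @return Named list of two [clone_callset()]s.
#' @export
sim_callsets <- function(sim) {
  mk <- function(sample_name) {
    s <- sim$samples[[sample_name]]
    df <- data.frame(chrom = sim$sites$chrom, pos = sim$sites$pos,
                     ref = sim$sites$ref, alt = sim$sites$alt,
                     vtype = sim$sites$vtype, qual = sim$sites$qual,
                     FS = sim$sites$FS, QD = sim$sites$QD,
                     MQ = sim$sites$MQ, SOR = sim$sites$SOR,
                     MQRankSum = sim$sites$MQRankSum,
                     ReadPosRankSum = sim$sites$ReadPosRankSum,
                     gt = s$gt, depth = s$depth, alt_reads = s$alt_reads,
                     n_alt = 1L, stringsAsFactors = FALSE)
    clone_callset(df, sample_name)
  }
  setNames(lapply(names(sim$samples), mk), names(sim$samples))
}

#' Simulate a per-base coverage track with fractional-depth CNVs
#'
#' Baseline depth `mean_depth` multiplied inside each CNV interval; Poisson
#' noise per position (or exact rounded depths with
#' `model = "constant"`). N positions report depth 0.
#'
#' @param genome A `genome_sequence`.
#' @param cnv_mults Data frame `chrom`, `start`, `end` (0-based half-open),
#'   `mult`; may be `NULL`.
#' @param seed Integer seed.
#' @param mean_depth Baseline depth (default 30).
#' @param model "poisson" (default) or "constant".
#' @return Data frame `chrom`, `pos` (1-based), `depth`.
#' @export
simulate_coverage <- function(genome, cnv_mults, seed, mean_depth = 30,
                              model = c("poisson", "constant")) {
  model <- match.arg(model)
  check_genome(genome)
  with_seed(seed, {
    out <- lapply(names(genome), function(chrom) {
      len <- nchar(unclass(genome)[[chrom]])
      mult <- rep(1, len)
      if (!is.null(cnv_mults) && nrow(cnv_mults)) {
        sel <- cnv_mults$chrom == chrom
        for (i in which(sel)) {
          mult[(cnv_mults$start[i] + 1L):cnv_mults$end[i]] <-
            cnv_mults$mult[i]
        }
      }
      depth <- if (model == "poisson") {
        rpois(len, mean_depth * mult)
      } else {
        as.integer(round(mean_depth * mult))
      }
      is_n <- charToRaw(unclass(genome)[[chrom]]) == charToRaw("N")
      depth[is_n] <- 0L
      data.frame(chrom = chrom, pos = seq_len(len), depth = depth,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate a methylation cohort with a planted strain effect
#'
#' Builds a sample sheet over tissue x sex x strain strata with ages drawn
#' uniformly, and a probes x samples beta matrix where B6 samples in the
#' effect tissues carry `+delta_beta` at the effect probes; values are
#' clipped to \[0, 1\].
#'
#' @param seed Integer seed.
#' @param tissues Character vector of tissues.
#' @param n_per_stratum Samples per strain per (tissue, sex) stratum.
#' @param n_probes Number of probes.
#' @param n_effect_probes,n_effect_tissues Planted effect extent.
#' @param delta_beta Planted beta difference (B6 minus 129Sv).
#' @param noise_sd Per-sample Gaussian noise SD.
#' @param age_range Inclusive age range in days.
#' @return List: `metadata`, `beta`, `truth`.
#' @export
simulate_methylation <- function(seed,
                                 tissues = c("liver", "kidney", "lung",
                                             "spleen", "heart", "brain",
                                             "blood"),
                                 n_per_stratum = 8L, n_probes = 12L,
                                 n_effect_probes = 2L,
                                 n_effect_tissues = 2L, delta_beta = 0.15,
                                 noise_sd = 0.04,
                                 age_range = c(0L, 365L)) {
  stopifnot(n_effect_probes <= n_probes,
            n_effect_tissues <= length(tissues))
  with_seed(seed, {
    grid <- expand.grid(strain = c("129Sv", "B6"), tissue = tissues,
                        sex = c("F", "M"), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    meta <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
      data.frame(sample_id = sprintf("%s_%s_%s_%02d", grid$strain[r],
                                     grid$tissue[r], grid$sex[r],
                                     seq_len(n_per_stratum)),
                 strain = grid$strain[r], tissue = grid$tissue[r],
                 sex = grid$sex[r],
                 age_days = sample(age_range[1]:age_range[2],
                                   n_per_stratum, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    probes <- sprintf("cg%07d", seq_len(n_probes))
    effect_probes <- probes[seq_len(n_effect_probes)]
    effect_tissues <- tissues[seq_len(n_effect_tissues)]
    baseline <- runif(n_probes, 0.1, 0.7)
    beta <- matrix(NA_real_, n_probes, nrow(meta),
                   dimnames = list(probes, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      eff <- (meta$strain[j] == "B6" &
                meta$tissue[j] %in% effect_tissues) *
        delta_beta * (probes %in% effect_probes)
      beta[, j] <- pmin(pmax(baseline + eff +
                               rnorm(n_probes, 0, noise_sd), 0), 1)
    }
    list(metadata = meta, beta = beta,
         truth = list(effect_probes = effect_probes,
                      effect_tissues = effect_tissues,
                      delta_beta = delta_beta, noise_sd = noise_sd))
  })
}

simulate_sv_candidates <- function(genome, seed, n_unique = 4L,
                                   n_low_support = 2L, n_shared = 2L) {
  lens <- chrom_lengths(genome)
  with_seed(seed, {
    rand_bp <- function(n) {
      ca <- sample(names(lens), n, replace = TRUE)
      cb <- sample(names(lens), n, replace = TRUE)
      data.frame(chrom_a = ca,
                 pos_a = vapply(ca, function(c) {
                   sample.int(lens[[c]] - 2000L, 1L) + 1000L
                 }, integer(1)),
                 chrom_b = cb,
                 pos_b = vapply(cb, function(c) {
                   sample.int(lens[[c]] - 2000L, 1L) + 1000L
                 }, integer(1)),
                 sv_type = "CTX", stringsAsFactors = FALSE)
    }
    uniq <- rand_bp(n_unique)
    uniq$supporting_reads <- sample(3:10, n_unique, replace = TRUE)
    low <- rand_bp(n_low_support)
    low$supporting_reads <- sample(1:2, n_low_support, replace = TRUE)
    shared <- rand_bp(n_shared)
    shared$supporting_reads <- sample(3:10, n_shared, replace = TRUE)
    shared_b <- shared
    shared_b$pos_a <- shared_b$pos_a + sample(-500:500, n_shared,
                                              replace = TRUE)
    shared_b$pos_b <- shared_b$pos_b + sample(-500:500, n_shared,
                                              replace = TRUE)
    b_only <- rand_bp(2L)
    b_only$supporting_reads <- sample(3:10, 2L, replace = TRUE)
    list(sv_a = rbind(uniq, low, shared),
         sv_b = rbind(shared_b, b_only),
         truth = list(n_unique_supported = n_unique))
  })
}

#' Simulate a complete study dataset on disk
#'
#' Generates every input the pipeline consumes — reference FASTA, a joint
#' two-clone VCF, two coverage TSVs, off-target site/region BEDs, CNV call
#' TSVs, SV candidate TSVs, a methylation sample sheet and beta matrix —
#' plus a JSON truth file recording everything planted. Byte-identical
#' output for identical seeds.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param params [default_sim_params()] list.
#' @return Invisible list with all in-memory objects, truth, and file
#'   paths.
#' @export
simulate_dataset <- function(dir, seed, params = default_sim_params()) {
  p <- params
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome0 <- make_genome(sub_seed(seed, 1L), p$chrom_lengths, p$n_blocks)
  guide <- with_seed(sub_seed(seed, 2L), guide_spec(
    paste(sample(c("A", "C", "G", "T"), p$guide_length, replace = TRUE),
          collapse = ""),
    pam_pattern = p$pam_search, max_mismatches = 7L, bulge_size = 1L))
  planted <- plant_offtargets(genome0, guide, p$category_counts,
                              seed = sub_seed(seed, 3L),
                              flank = p$region_flank)
  genome <- planted$genome
  regions <- data.frame(chrom = planted$truth$chrom,
                        start = planted$truth$region_start,
                        end = planted$truth$region_end,
                        stringsAsFactors = FALSE)
  sim <- simulate_clone_callsets(genome, regions, sub_seed(seed, 4L), p)

  cnv_tracks_a <- rbind(
    p$cnvs_a[, c("chrom", "start", "end", "mult")],
    p$cnvs_shared[, c("chrom", "start", "end", "mult")],
    p$artifacts_a[, c("chrom", "start", "end", "mult")])
  cnv_tracks_b <- p$cnvs_shared[, c("chrom", "start", "end", "mult")]
  cov_a <- simulate_coverage(genome, cnv_tracks_a, sub_seed(seed, 5L),
                             p$mean_depth, p$coverage_model)
  cov_b <- simulate_coverage(genome, cnv_tracks_b, sub_seed(seed, 6L),
                             p$mean_depth, p$coverage_model)
  sv <- simulate_sv_candidates(genome, sub_seed(seed, 7L), p$n_sv_unique,
                               p$n_sv_low_support, p$n_sv_shared)
  meth <- simulate_methylation(sub_seed(seed, 8L), p$tissues,
                               p$n_per_stratum, p$n_probes,
                               p$n_effect_probes, p$n_effect_tissues,
                               p$delta_beta, p$noise_sd, p$age_range)

  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    vcf = file.path(dir, "clones.vcf"),
    coverage_a = file.path(dir, paste0("coverage_", p$clone_a, ".tsv")),
    coverage_b = file.path(dir, paste0("coverage_", p$clone_b, ".tsv")),
    sites_bed = file.path(dir, "offtarget_sites.bed"),
    regions_bed = file.path(dir, "offtarget_regions.bed"),
    cnv_a = file.path(dir, paste0("cnv_", p$clone_a, ".tsv")),
    cnv_b = file.path(dir, paste0("cnv_", p$clone_b, ".tsv")),
    sv_a = file.path(dir, paste0("sv_", p$clone_a, ".tsv")),
    sv_b = file.path(dir, paste0("sv_", p$clone_b, ".tsv")),
    sample_sheet = file.path(dir, "samples.csv"),
    beta = file.path(dir, "beta.tsv"),
    truth = file.path(dir, "truth.json"))

  write_fasta(genome, paths$fasta)
  write_joint_vcf(sim$sites, sim$samples, paths$vcf,
                  contigs = chrom_lengths(genome))
  write_coverage(cov_a, paths$coverage_a)
  write_coverage(cov_b, paths$coverage_b)
  tr <- planted$truth
  write_bed(data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                       label = sprintf("MM%d;%s;%s", tr$mismatches,
                                       tr$pam_class, tr$bulge)),
            paths$sites_bed)
  write_bed(regions, paths$regions_bed)
  # CNV call lists, 1-based inclusive on disk (cnv dialect)
  cnv_out <- function(calls, path) {
    data.table::fwrite(data.frame(chrom = calls$chrom,
                                  start = calls$start + 1L,
                                  end = calls$end, type = calls$cnv_type),
                       path, sep = "\t", col.names = FALSE)
  }
  cnv_out(rbind(p$cnvs_a[, c("chrom", "start", "end", "cnv_type")],
                p$cnvs_shared[, c("chrom", "start", "end", "cnv_type")]),
          paths$cnv_a)
  cnv_out(p$cnvs_shared[, c("chrom", "start", "end", "cnv_type")],
          paths$cnv_b)
  sv_out <- function(svs, path) {
    data.table::fwrite(svs[, c("chrom_a", "pos_a", "chrom_b", "pos_b",
                               "sv_type", "supporting_reads")],
                       path, sep = "\t", col.names = FALSE)
  }
  sv_out(sv$sv_a, paths$sv_a)
  sv_out(sv$sv_b, paths$sv_b)
  data.table::fwrite(meth$metadata, paths$sample_sheet)
  beta_df <- data.frame(probe = rownames(meth$beta),
                        signif(meth$beta, 6), check.names = FALSE)
  data.table::fwrite(beta_df, paths$beta, sep = "\t")

  truth <- list(seed = seed,
                guide = list(protospacer = guide$protospacer,
                             pam_pattern = guide$pam_pattern),
                offtargets = planted$truth,
                offtarget_background_n = nrow(planted$background),
                callsets = sim$truth,
                cnvs_a = p$cnvs_a, cnvs_shared = p$cnvs_shared,
                artifacts_a = p$artifacts_a,
                sv = sv$truth,
                methylation = meth$truth)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(genome = genome, guide = guide, planted = planted,
                 sim = sim, coverage_a = cov_a, coverage_b = cov_b,
                 sv = sv, meth = meth, regions = regions, truth = truth,
                 paths = paths, params = p))
}
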