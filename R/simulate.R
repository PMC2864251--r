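#' Simulate a multi-tissue, two-strain miRNA count matrix
#'
#' Emulates the structure of a six-tissue, two-strain small RNA DGE
#' experiment at desk scale: heavy-tailed (log-normal) baseline expression
#' shared across tissues, negative-binomial count noise (replicate
#' variation between individual animals is overdispersed relative to
#' Poisson), liver triplicates, single libraries elsewhere. Planted
#' tissue-specific rows are multiplied by their fold in the focal tissue in
#' both strains; planted strain effects multiply every liver replicate of
#' the focal strain.
#'
#' @param seed integer RNG seed; identical seeds give identical matrices.
#' @param n_mirnas number of miRNA-arm rows (default 500).
#' @param tissues,strains sample structure (defaults: the six-tissue,
#'   BN-Lx/SHR design).
#' @param liver_replicates replicates for liver (default 3); other tissues
#'   get one library per strain.
#' @param meanlog,sdlog log-normal baseline expression parameters on the
#'   count scale (defaults log(50) and 1.5: median 50, heavy right tail).
#' @param dispersion negative-binomial size parameter (default 100, i.e.
#'   ~10% extra-Poisson CV between replicates; at abundant rows this is
#'   several-fold-Poisson variance). `NULL` disables noise (counts are the
#'   rounded expectations), which is what threshold-boundary experiments
#'   use.
#' @param planted_specific `NULL` or data frame (`row`, `tissue`, `fold`).
#' @param planted_strain `NULL` or data frame (`row`, `fold`, `strain`):
#'   liver expression of `row` is multiplied by `fold` in `strain`.
#' @param planted_base baseline expectation assigned to planted rows so
#'   their recovery is a coverage-controlled property (default 200).
#' @return List with `counts` (a [count_matrix]) and `truth` (the planted
#'   effect tables).
#' @export
simulate_counts <- function(seed, n_mirnas = 500,
                            tissues = c("brain", "liver", "spleen", "heart",
                                        "testis", "kidney"),
                            strains = c("BN-Lx", "SHR"),
                            liver_replicates = 3,
                            meanlog = log(50), sdlog = 1.5, dispersion = 100,
                            planted_specific = NULL, planted_strain = NULL,
                            planted_base = 200) {
  with_seed(seed, {
    rows <- sprintf("mir-%03d", seq_len(n_mirnas))
    base <- stats::rlnorm(n_mirnas, meanlog, sdlog)
    names(base) <- rows
    planted_rows <- unique(c(planted_specific$row, planted_strain$row))
    if (!is.null(planted_base) && length(planted_rows) > 0)
      base[planted_rows] <- planted_base
    smp <- list()
    for (t in tissues) for (s in strains) {
      reps <- if (t == "liver") seq_len(liver_replicates) else 1L
      for (r in reps)
        smp[[length(smp) + 1L]] <- data.frame(tissue = t, strain = s,
                                              replicate = r,
                                              stringsAsFactors = FALSE)
    }
    smp <- do.call(rbind, smp)
    smp$label <- paste(smp$tissue, smp$strain, smp$replicate, sep = ".")
    counts <- matrix(0L, n_mirnas, nrow(smp), dimnames = list(rows, smp$label))
    for (j in seq_len(nrow(smp))) {
      mu <- base
      if (!is.null(planted_specific) && nrow(planted_specific) > 0) {
        hit <- planted_specific$tissue == smp$tissue[j]
        if (any(hit))
          mu[planted_specific$row[hit]] <-
            mu[planted_specific$row[hit]] * planted_specific$fold[hit]
      }
      if (!is.null(planted_strain) && nrow(planted_strain) > 0 &&
          smp$tissue[j] == "liver") {
        hit <- planted_strain$strain == smp$strain[j]
        if (any(hit))
          mu[planted_strain$row[hit]] <-
            mu[planted_strain$row[hit]] * planted_strain$fold[hit]
      }
      counts[, j] <- if (is.null(dispersion)) round(mu)
                     else stats::rnbinom(n_mirnas, mu = mu, size = dispersion)
    }
    list(counts = count_matrix(counts, smp[c("label", "tissue", "strain",
                                             "replicate")]),
         truth = list(specific = planted_specific, strain = planted_strain))
  })
}

#' Simulate miRNA reads carrying planted A-to-G editing
#'
#' Builds one synthetic locus per requested precursor (an 80-nt precursor
#' with a 22-nt mature 5p arm) together with its genome sequence and
#' annotation, then emits `coverage` reads over the arm, each independently
#' edited (a single A-to-G substitution at the planted precursor position)
#' with probability `rate`, the remainder perfect.
#'
#' @param seed integer RNG seed.
#' @param sites data frame with columns `precursor` (name), `position`
#'   (0-based offset on the precursor; must fall inside the 5p arm,
#'   precursor offsets 10..31), `rate` (editing probability in \[0, 1\]).
#' @param coverage reads per precursor (default 500).
#' @param strand genome strand of the precursors (default `"+"`; `"-"`
#'   exercises the orientation logic).
#' @param sample sample label attached to the reads.
#' @param exact if `TRUE`, exactly `round(rate * coverage)` reads are
#'   edited (deterministic mixture, used for threshold-boundary
#'   experiments); if `FALSE` (default) each read is edited independently
#'   with probability `rate`.
#' @return List with `reads` ([aligned_reads]), `ann` ([annotation_set]),
#'   `genome` ([Biostrings::DNAStringSet]), and `truth` (the `sites` input).
#' @export
simulate_editing_reads <- function(seed, sites, coverage = 500,
                                   strand = "+",
                                   sample = "brain.BN-Lx.1",
                                   exact = FALSE) {
  stopifnot(all(sites$rate >= 0 & sites$rate <= 1),
            all(sites$position >= 10 & sites$position < 32))
  arm_off <- c(10L, 32L)  # 5p arm at precursor offsets [10, 32)
  pre_len <- 80L
  flank <- 100L
  with_seed(seed, {
    genome <- list(); ann <- list(); reads <- list()
    for (r in seq_len(nrow(sites))) {
      pname <- sites$precursor[r]
      ppos <- as.integer(sites$position[r])
      rate <- sites$rate[r]
      chrom <- paste0("chrE_", pname)
      pseq <- sample(c("A", "C", "G", "T"), pre_len, replace = TRUE)
      pseq[ppos + 1L] <- "A"  # the editable adenosine
      chrom_len <- flank * 2L + pre_len
      # genome forward strand carrying the precursor at offset `flank`
      if (strand == "+") {
        fwd <- c(sample(c("A", "C", "G", "T"), flank, TRUE), pseq,
                 sample(c("A", "C", "G", "T"), flank, TRUE))
        pre_start <- flank
      } else {
        fwd <- c(sample(c("A", "C", "G", "T"), flank, TRUE),
                 rev(chartr("ACGT", "TGCA", pseq)),
                 sample(c("A", "C", "G", "T"), flank, TRUE))
        pre_start <- flank
      }
      pre_end <- pre_start + pre_len
      genome[[chrom]] <- paste(fwd, collapse = "")
      # arm genome coordinates
      if (strand == "+") {
        arm_start <- pre_start + arm_off[1]; arm_end <- pre_start + arm_off[2]
      } else {
        arm_start <- pre_end - arm_off[2]; arm_end <- pre_end - arm_off[1]
      }
      ann[[length(ann) + 1L]] <- data.frame(
        chrom = chrom,
        start = c(pre_start, arm_start), end = c(pre_end, arm_end),
        strand = strand, class = c("pre_mirna", "mirna_arm"),
        name = c(pname, paste0(pname, "-5p")),
        parent = c(NA_character_, pname), stringsAsFactors = FALSE)
      # reads: the mature arm sequence, edited with probability `rate`
      arm_seq <- paste(pseq[(arm_off[1] + 1L):arm_off[2]], collapse = "")
      read_off <- ppos - arm_off[1]  # offset of the site on the arm (5' end)
      edited <- if (exact) seq_len(coverage) <= round(rate * coverage)
                else stats::runif(coverage) < rate
      for (i in seq_len(coverage)) {
        sq <- arm_seq
        mm <- NULL
        if (edited[i]) {
          substr(sq, read_off + 1L, read_off + 1L) <- "G"
          mm <- list(data.frame(offset = read_off, ref = "A", read = "G",
                                stringsAsFactors = FALSE))
        }
        reads[[length(reads) + 1L]] <- aligned_reads(
          read_id = sprintf("%s_r%04d", pname, i), chrom = chrom,
          start = arm_start, end = arm_end, strand = strand, sequence = sq,
          copies = 1L, mismatches = mm, sample = sample)
      }
    }
    ann <- do.call(rbind, ann)
    list(reads = do.call(bind_reads, reads),
         ann = annotation_set(ann$chrom, ann$start, ann$end, ann$strand,
                              ann$class, ann$name, ann$parent),
         genome = Biostrings::DNAStringSet(unlist(genome)),
         truth = sites)
  })
}

#' Simulate repeat-derived reads under the ping-pong mechanism
#'
#' Primary plus-strand reads with a 5'-terminal U are placed at random in
#' the region; each primary spawns a secondary minus-strand read whose 5'
#' end sits opposite position 10 of its guide, creating the diagnostic
#' 10-nt 5'-5' overlap (and, by complementarity, an A at the secondary's
#' position 10). Background reads are placed uniformly on both strands.
#'
#' @param seed integer RNG seed.
#' @param n_pairs number of primary/secondary pairs (default 1000).
#' @param background_fraction fraction of all reads that are uniform
#'   background (default 0.3); `1` yields background only.
#' @param region_length region size in bp (default 50000).
#' @param read_length piRNA-like read length (default 27).
#' @return List with `reads` ([aligned_reads]), `region_sequence`
#'   (character), and `truth` (ids of primary/secondary/background reads).
#' @export
simulate_pingpong_reads <- function(seed, n_pairs = 1000,
                                    background_fraction = 0.3,
                                    region_length = 50000,
                                    read_length = 27) {
  stopifnot(background_fraction >= 0, background_fraction <= 1)
  with_seed(seed, {
    L <- as.integer(region_length)
    region <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (background_fraction >= 1) {
      n_pairs_eff <- 0L
      n_bg <- 2L * n_pairs
    } else {
      n_pairs_eff <- n_pairs
      n_bg <- round(background_fraction / (1 - background_fraction) *
                      2 * n_pairs)
    }
    reads <- list()
    if (n_pairs_eff > 0) {
      p_start <- sample(seq(20L, L - 2L * read_length), n_pairs_eff,
                        replace = TRUE)
      region[p_start + 1L] <- "T"  # 5' U on every primary guide
      extract <- function(s, e) paste(region[(s + 1L):e], collapse = "")
      prim_seq <- vapply(seq_len(n_pairs_eff), function(i)
        extract(p_start[i], p_start[i] + read_length), character(1))
      # secondary: minus strand, 5' end opposite guide position 10
      s_end <- p_start + 10L
      s_start <- s_end - read_length
      sec_seq <- vapply(seq_len(n_pairs_eff), function(i)
        revcomp(extract(s_start[i], s_end[i])), character(1))
      reads[[1]] <- aligned_reads(
        read_id = sprintf("prim%05d", seq_len(n_pairs_eff)), chrom = "region",
        start = p_start, end = p_start + read_length, strand = "+",
        sequence = prim_seq)
      reads[[2]] <- aligned_reads(
        read_id = sprintf("sec%05d", seq_len(n_pairs_eff)), chrom = "region",
        start = s_start, end = s_end, strand = "-", sequence = sec_seq)
    }
    if (n_bg > 0) {
      b_start <- sample(seq(0L, L - read_length), n_bg, replace = TRUE)
      b_strand <- sample(c("+", "-"), n_bg, replace = TRUE)
      b_seq <- vapply(seq_len(n_bg), function(i) {
        s <- paste(region[(b_start[i] + 1L):(b_start[i] + read_length)],
                   collapse = "")
        if (b_strand[i] == "-") revcomp(s) else s
      }, character(1))
      reads[[length(reads) + 1L]] <- aligned_reads(
        read_id = sprintf("bg%05d", seq_len(n_bg)), chrom = "region",
        start = b_start, end = b_start + read_length, strand = b_strand,
        sequence = b_seq)
    }
    all_reads <- do.call(bind_reads, reads)
    list(reads = all_reads, region_sequence = paste(region, collapse = ""),
         truth = list(
           primary = grep("^prim", all_reads$read_id, value = TRUE),
           secondary = grep("^sec", all_reads$read_id, value = TRUE),
           background = grep("^bg", all_reads$read_id, value = TRUE)))
  })
}

#' Simulate strand-specific piRNA cluster reads with annotation tracks
#'
#' Plants `k` strand-specific clusters of dense unique 5' starts on a
#' synthetic chromosome over a sparse uniform background; a configurable
#' fraction of clusters is arranged as divergent opposite-strand pairs
#' sharing a central boundary. Gene, repeat and conservation tracks are
#' generated with separate inside/outside densities so cluster
#' characterization has a planted truth.
#'
#' @param seed integer RNG seed.
#' @param genome_length chromosome length in bp (default 1e7).
#' @param k number of planted clusters (default 10).
#' @param cluster_length_range min/max planted cluster length (default
#'   5-20 kb).
#' @param starts_per_2kb unique-start density inside clusters (default 30).
#' @param background_per_10kb total background unique-start density across
#'   both strands (default 1 per 10 kb, split evenly).
#' @param divergent_fraction fraction of the `k` clusters arranged as
#'   divergent pairs (default 0.3).
#' @param read_length read length (default 27).
#' @param gene_density_in,gene_density_out genes per Mb inside/outside
#'   clusters (defaults 8 and 4).
#' @param repeat_frac_in,repeat_frac_out repeat base fraction
#'   inside/outside (defaults 0.05 and 0.3).
#' @param cons_frac_in,cons_frac_out conserved base fraction inside/outside
#'   (defaults 0.02 and 0.05).
#' @return List with `reads`, `truth` (planted cluster BED-like table),
#'   `genes`, `repeats`, `conservation`, `chrom_lengths`.
#' @export
simulate_cluster_reads <- function(seed, genome_length = 1e7, k = 10,
                                   cluster_length_range = c(5000, 20000),
                                   starts_per_2kb = 30,
                                   background_per_10kb = 1,
                                   divergent_fraction = 0.3,
                                   read_length = 27,
                                   gene_density_in = 8, gene_density_out = 4,
                                   repeat_frac_in = 0.05,
                                   repeat_frac_out = 0.3,
                                   cons_frac_in = 0.02,
                                   cons_frac_out = 0.05) {
  with_seed(seed, {
    L <- as.integer(genome_length)
    chrom <- "chrS"
    n_div_pairs <- floor(k * divergent_fraction / 2)
    # lay out k cluster slots with generous spacing
    slot_w <- L %/% max(k, 1L)
    truth <- list()
    if (k > 0) for (i in seq_len(k)) {
      len <- round(stats::runif(1, cluster_length_range[1],
                                cluster_length_range[2]))
      lo <- (i - 1L) * slot_w + 25000L
      hi <- i * slot_w - 25000L - len
      cstart <- round(stats::runif(1, lo, hi))
      truth[[i]] <- data.frame(chrom = chrom, start = cstart,
                               end = cstart + len,
                               strand = sample(c("+", "-"), 1),
                               pair = NA_integer_, stringsAsFactors = FALSE)
    }
    truth <- if (length(truth) > 0) do.call(rbind, truth)
             else data.frame(chrom = character(0), start = integer(0),
                             end = integer(0), strand = character(0),
                             pair = integer(0), stringsAsFactors = FALSE)
    # convert the first 2*n_div_pairs clusters into abutting divergent pairs
    if (n_div_pairs > 0) for (p in seq_len(n_div_pairs)) {
      i <- 2L * p - 1L; j <- 2L * p
      mid <- truth$start[i] + (truth$end[i] - truth$start[i]) %/% 2L
      w_j <- truth$end[j] - truth$start[j]
      truth$end[i] <- mid
      truth$strand[i] <- "-"      # upstream member, pointing left
      truth$start[j] <- mid + 200L
      truth$end[j] <- mid + 200L + w_j
      truth$strand[j] <- "+"      # downstream member, pointing right
      truth$pair[c(i, j)] <- p
    }
    starts <- list()
    if (k > 0) for (i in seq_len(k)) {
      len <- truth$end[i] - truth$start[i]
      n <- ceiling(len / 2000 * starts_per_2kb)
      pos <- truth$start[i] +
        sort(unique(sample.int(len, min(n, len), replace = FALSE))) - 1L
      starts[[length(starts) + 1L]] <-
        data.frame(pos = pos, strand = truth$strand[i],
                   stringsAsFactors = FALSE)
    }
    n_bg_per_strand <- round(L / 10000 * background_per_10kb / 2)
    for (st in c("+", "-"))
      starts[[length(starts) + 1L]] <-
        data.frame(pos = sample.int(L - 2L * read_length, n_bg_per_strand) +
                     read_length,
                   strand = st, stringsAsFactors = FALSE)
    starts <- do.call(rbind, starts)
    starts <- unique(starts)
    # materialize reads from 5' starts
    is_plus <- starts$strand == "+"
    rstart <- ifelse(is_plus, starts$pos, starts$pos - read_length + 1L)
    reads <- aligned_reads(
      read_id = sprintf("pi%06d", seq_len(nrow(starts))), chrom = chrom,
      start = rstart, end = rstart + read_length, strand = starts$strand)
    # annotation tracks with planted inside/outside densities
    cluster_iv <- truth[c("chrom", "start", "end")]
    genes <- plant_track(cluster_iv, L, chrom, width = 2000,
                         n_in = round(gene_density_in * sum(truth$end - truth$start) / 1e6),
                         n_out = round(gene_density_out * (L - sum(truth$end - truth$start)) / 1e6))
    repeats <- plant_track(cluster_iv, L, chrom, width = 500,
                           n_in = round(repeat_frac_in * sum(truth$end - truth$start) / 500),
                           n_out = round(repeat_frac_out * (L - sum(truth$end - truth$start)) / 500))
    cons <- plant_track(cluster_iv, L, chrom, width = 200,
                        n_in = round(cons_frac_in * sum(truth$end - truth$start) / 200),
                        n_out = round(cons_frac_out * (L - sum(truth$end - truth$start)) / 200))
    gene_ann <- annotation_set(genes$chrom, genes$start, genes$end, "+",
                               "gene", sprintf("gene%05d", seq_len(nrow(genes))))
    rep_ann <- annotation_set(repeats$chrom, repeats$start, repeats$end, "+",
                              "repeat",
                              sprintf("rep%05d", seq_len(nrow(repeats))))
    conservation <- data.frame(chrom = cons$chrom, start = cons$start,
                               end = cons$end, score = 0.8,
                               stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, genes = gene_ann, repeats = rep_ann,
         conservation = conservation,
         chrom_lengths = stats::setNames(L, chrom))
  })
}

# Place `n_in` intervals uniformly inside the cluster intervals and `n_out`
# uniformly outside them (non-overlap between placed intervals is not
# enforced; densities are what matters).
plant_track <- function(clusters, L, chrom, width, n_in, n_out) {
  out <- list()
  if (n_in > 0 && nrow(clusters) > 0) {
    w <- clusters$end - clusters$start - width
    w[w < 1] <- 1
    pick <- sample.int(nrow(clusters), n_in, replace = TRUE, prob = w)
    s <- clusters$start[pick] +
      floor(stats::runif(n_in) * w[pick])
    out[[1]] <- data.frame(chrom = chrom, start = s, end = s + width,
                           stringsAsFactors = FALSE)
  }
  if (n_out > 0) {
    # rejection-sample outside positions
    s <- integer(0)
    while (length(s) < n_out) {
      cand <- sample.int(L - width, n_out - length(s))
      if (nrow(clusters) > 0) {
        bad <- vapply(cand, function(x)
          any(x < clusters$end & x + width > clusters$start), logical(1))
        cand <- cand[!bad]
      }
      s <- c(s, cand)
    }
    out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = s,
                                          end = s + width,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}
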