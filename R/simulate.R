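# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, freqs = uniform_background()) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = freqs), collapse = "")
}

#' Specification of a bipartite binding-site motif
#'
#' Describes the site population the generator draws from: two conserved
#' pentamers around a random spacer, mimicking the CpxR box
#' `GTAAA-N5-6-GTAAA`. Each pentamer base is retained with probability
#' `identity` and otherwise substituted uniformly among the other three
#' bases; spacer bases are i.i.d. uniform.
#'
#' @param left,right pentamer consensus strings (defaults `"GTAAA"`).
#' @param spacer_probs probability of each spacer length, named vector over
#'   `"5"` and `"6"` (default: always 5, matching the curated 15-bp set).
#' @param identity per-position retention probability in `(0, 1]`.
#' @param seed integer RNG seed.
#' @return A list of class `"cpx_motif_spec"`.
#' @export
motif_spec <- function(left = "GTAAA", right = "GTAAA",
                       spacer_probs = c("5" = 1, "6" = 0),
                       identity = 0.9, seed = 1L) {
  left <- toupper(left); right <- toupper(right)
  if (grepl("[^ACGT]", left) || grepl("[^ACGT]", right)) {
    stop("pentamers must be over A/C/G/T")
  }
  if (!identical(sort(names(spacer_probs)), c("5", "6")) ||
      any(spacer_probs < 0) || abs(sum(spacer_probs) - 1) > 1e-9) {
    stop("spacer_probs must be probabilities named '5' and '6' summing to 1")
  }
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
  structure(list(left = left, right = right, spacer_probs = spacer_probs,
                 identity = identity, seed = as.integer(seed)),
            class = "cpx_motif_spec")
}

mutate_consensus <- function(consensus, identity) {
  bases <- strsplit(consensus, "")[[1L]]
  keep <- stats::runif(length(bases)) <= identity
  subs <- vapply(bases[!keep], function(b) sample(setdiff(DNA_BASES, b), 1L),
                 character(1L))
  bases[!keep] <- subs
  paste(bases, collapse = "")
}

draw_site <- function(spec, spacer_len) {
  paste0(mutate_consensus(spec$left, spec$identity),
         random_dna(spacer_len),
         mutate_consensus(spec$right, spec$identity))
}

#' Sample noisy binding sites around the bipartite consensus
#'
#' Draws `n` sites per [motif_spec()]. When the spacer-length distribution
#' is degenerate the result is a single [binding_sites()] collection; when
#' both lengths occur, a list with elements `len15` and `len16` is
#' returned (aligned collections must be single-length).
#'
#' @param spec a [motif_spec()].
#' @param n number of sites (>= 1).
#' @return A `"cpx_sites"` collection, or a list of two.
#' @export
sample_sites <- function(spec, n) {
  stopifnot(inherits(spec, "cpx_motif_spec"), n >= 1L)
  with_seed(spec$seed, {
    lens <- 5L + (stats::runif(n) < spec$spacer_probs[["6"]])
    sites <- vapply(lens, function(sl) draw_site(spec, sl), character(1L))
  })
  if (length(unique(lens)) == 1L) {
    binding_sites(sites)
  } else {
    list(len15 = binding_sites(sites[lens == 5L]),
         len16 = binding_sites(sites[lens == 6L]))
  }
}

# One exemplar layout per location group, in local slot coordinates.
# Each entry: gene CDS intervals (0-based half-open), strands, planted box
# start offsets with strands, and which genes are the focal candidates.
SLOT_WIDTH <- 5000L

slot_layout <- function(class, box_len) {
  switch(class,
    A = list(genes = data.frame(off_start = c(800L, 1830L),
                                off_end = c(1800L, 2700L),
                                strand = c("+", "+")),
             boxes = data.frame(off = c(400L, 500L), strand = c("+", "+")),
             focal = 1L),
    B = list(genes = data.frame(off_start = 800L, off_end = 1700L,
                                strand = "+"),
             boxes = data.frame(off = c(400L, 500L), strand = c("+", "+")),
             focal = 1L),
    C = list(genes = data.frame(off_start = c(300L, 1600L),
                                off_end = c(1100L, 2500L),
                                strand = c("-", "+")),
             boxes = data.frame(off = 1300L, strand = "-"),
             focal = c(1L, 2L)),
    D = list(genes = data.frame(off_start = 800L, off_end = 1700L,
                                strand = "+"),
             boxes = data.frame(off = 400L, strand = "+"),
             focal = 1L),
    stop("unknown class ", class)
  )
}

#' Generate a genome with binding sites planted in promoter windows
#'
#' Emits an i.i.d.-background genome with non-overlapping gene models and,
#' for each requested location group (A-D), one exemplar of the
#' corresponding box layout planted inside the appropriate promoter
#' window(s):
#' A — two boxes upstream of the lead gene of a two-gene same-strand
#' cluster; B — two boxes upstream of a lone gene; C — one box in the
#' intergenic span shared by a divergent gene pair, inside both windows;
#' D — one box upstream of a lone gene. Optional decoy genes carry no
#' boxes. Everything is a pure function of the spec and seed.
#'
#' @param site_spec a [motif_spec()] governing the planted site sequences
#'   (use `identity = 1` for exact-consensus planting).
#' @param class_layout named integer vector: how many exemplars of each
#'   group, e.g. `c(A = 1, B = 1, C = 1, D = 1)`.
#' @param n_decoys additional boxless genes.
#' @param genome_length total genome length in bp (default 50000).
#' @param background base frequencies of the background sequence.
#' @param seed integer seed.
#' @return A list of class `"cpx_planted"`: `genome`
#'   ([Biostrings::DNAStringSet], one contig `synth_contig`), `genes`
#'   ([gene_table()]), `truth` (data.frame of planted boxes: `contig`,
#'   `start0`, `end0`, `strand`, `length`, `class`, `gene_id` of the focal
#'   gene(s), comma-separated), `background`, `seed`, `site_spec`.
#' @export
plant_genome <- function(site_spec = motif_spec(identity = 1),
                         class_layout = c(A = 1L, B = 1L, C = 1L, D = 1L),
                         n_decoys = 0L, genome_length = 50000L,
                         background = uniform_background(), seed = 1L) {
  stopifnot(inherits(site_spec, "cpx_motif_spec"))
  box_len <- 10L + as.integer(names(which.max(site_spec$spacer_probs)))
  classes <- rep(names(class_layout), times = class_layout)
  n_slots <- length(classes) + n_decoys
  need <- 1000L + n_slots * SLOT_WIDTH + 1000L
  if (genome_length < need) {
    stop(sprintf("infeasible layout: %d slots need >= %d bp, genome has %d",
                 n_slots, need, genome_length))
  }
  contig <- "synth_contig"
  with_seed(seed, {
    seq_chr <- random_dna(genome_length, background)
    genes <- list()
    truth <- list()
    gn <- 0L
    for (si in seq_along(classes)) {
      u <- 1000L + (si - 1L) * SLOT_WIDTH
      lay <- slot_layout(classes[[si]], box_len)
      ids <- character(nrow(lay$genes))
      for (k in seq_len(nrow(lay$genes))) {
        gn <- gn + 1L
        ids[[k]] <- sprintf("g%03d_%s", gn, classes[[si]])
      }
      genes[[si]] <- data.frame(gene_id = ids, contig = contig,
                                strand = lay$genes$strand,
                                start0 = u + lay$genes$off_start,
                                end0 = u + lay$genes$off_end)
      focal <- paste(ids[lay$focal], collapse = ",")
      for (k in seq_len(nrow(lay$boxes))) {
        site <- draw_site(site_spec,
                          spacer_len = box_len - 10L)
        planted <- if (lay$boxes$strand[[k]] == "+") site else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
        s0 <- u + lay$boxes$off[[k]]
        substr(seq_chr, s0 + 1L, s0 + box_len) <- planted
        truth[[length(truth) + 1L]] <- data.frame(
          contig = contig, start0 = s0, end0 = s0 + box_len,
          strand = lay$boxes$strand[[k]], length = box_len,
          class = classes[[si]], gene_id = focal)
      }
    }
    if (n_decoys > 0L) {
      for (di in seq_len(n_decoys)) {
        u <- 1000L + (length(classes) + di - 1L) * SLOT_WIDTH
        gn <- gn + 1L
        genes[[length(classes) + di]] <- data.frame(
          gene_id = sprintf("g%03d_decoy", gn), contig = contig,
          strand = if (di %% 2L) "+" else "-",
          start0 = u + 800L, end0 = u + 1700L)
      }
    }
  })
  genes <- do.call(rbind, genes)
  genome <- Biostrings::DNAStringSet(stats::setNames(seq_chr, contig))
  if (!length(truth)) {
    truth <- list(data.frame(contig = character(), start0 = integer(),
                             end0 = integer(), strand = character(),
                             length = integer(), class = character(),
                             gene_id = character()))
  }
  structure(list(genome = genome,
                 genes = gene_table(genes$gene_id, genes$contig,
                                    genes$strand, genes$start0, genes$end0),
                 truth = do.call(rbind, truth),
                 background = background, seed = as.integer(seed),
                 site_spec = site_spec),
            class = "cpx_planted")
}

#' @export
print.cpx_planted <- function(x, ...) {
  cat(sprintf(
    "Planted genome: %d bp, %d genes, %d planted boxes (classes %s), seed %d\n",
    Biostrings::width(x$genome)[[1L]], nrow(x$genes), nrow(x$truth),
    paste(sort(unique(x$truth$class)), collapse = ","), x$seed))
  invisible(x)
}

#' Write a planted genome bundle to disk
#'
#' Emits `genome.fa` (FASTA), `genes.gff3` (GFF3 via
#' [rtracklayer::export()]) and `truth.bed` (BED6; name field
#' `class|focal_gene`), exactly as consumed by the scanning and annotation
#' stages.
#'
#' @param planted a [plant_genome()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_planted <- function(planted, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genes.gff3")
  bed <- file.path(dir, "truth.bed")
  Biostrings::writeXStringSet(planted$genome, fa)
  g <- planted$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(start = g$start0 + 1L, end = g$end0),
    strand = g$strand)
  gr$type <- "gene"
  gr$source <- "cpxscreen"
  gr$ID <- g$gene_id
  gr$locus_tag <- g$gene_id
  rtracklayer::export(gr, gff, format = "gff3")
  tr <- planted$truth
  write_bed6(data.frame(contig = tr$contig, start0 = tr$start0,
                        end0 = tr$end0,
                        name = paste0(tr$class, "|", tr$gene_id),
                        score = 0, strand = tr$strand),
             bed)
  invisible(c(fasta = fa, gff3 = gff, bed = bed))
}

#' Simulate a qRT-PCR Ct table with known effects
#'
#' Each gene has a baseline Ct; under a condition its Ct shifts by minus
#' the true log2 effect (an up-regulated gene amplifies earlier), plus
#' i.i.d. Gaussian replicate noise. The reference gene is constant in
#' expectation across conditions. With zero noise, [ddct_fold()] recovers
#' `2^effect` exactly.
#'
#' @param effects numeric matrix of true log2 effects, genes x conditions
#'   (dimnames required); the control condition is implicit (effect 0).
#' @param noise_sd replicate noise SD in Ct cycles (>= 0).
#' @param replicates replicates per (gene, condition) (>= 1).
#' @param baseline_ct mean baseline Ct; per-gene baselines are drawn
#'   uniformly within `baseline_ct` +/- 2.
#' @param reference,control reference gene and control condition ids.
#' @param seed integer seed.
#' @return A [ct_table()].
#' @export
simulate_ct <- function(effects, noise_sd = 0.2, replicates = 3L,
                        baseline_ct = 20, reference = "rpoD",
                        control = "control", seed = 1L) {
  stopifnot(is.matrix(effects), !is.null(rownames(effects)),
            !is.null(colnames(effects)), noise_sd >= 0, replicates >= 1L)
  if (!(reference %in% rownames(effects))) {
    effects <- rbind(effects,
                     matrix(0, 1L, ncol(effects),
                            dimnames = list(reference, colnames(effects))))
  }
  genes <- rownames(effects)
  conds <- c(control, colnames(effects))
  with_seed(seed, {
    base <- stats::setNames(stats::runif(length(genes), baseline_ct - 2,
                                         baseline_ct + 2), genes)
    rows <- expand.grid(replicate = seq_len(replicates), gene = genes,
                        condition = conds, stringsAsFactors = FALSE)
    eff <- numeric(nrow(rows))
    trt <- rows$condition != control
    eff[trt] <- effects[cbind(rows$gene[trt], rows$condition[trt])]
    rows$Ct <- base[rows$gene] - eff +
      stats::rnorm(nrow(rows), sd = noise_sd)
  })
  ct_table(rows[, c("gene", "condition", "replicate", "Ct")],
           reference = reference, control = control)
}
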