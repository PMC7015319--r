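#' Codon usage implied by tRNA abundances
#'
#' Each tRNA species' copy number is split equally among its cognate codons;
#' the per-codon contributions are summed over all species and (optionally)
#' normalised to frequencies. A transcriptome whose codon bias equals this
#' distribution places a demand on each tRNA species exactly proportional to
#' its abundance.
#'
#' @param trna_counts named numeric vector of tRNA copy numbers.
#' @param map a [decode_map()] covering the species in `trna_counts`.
#' @param normalize if `FALSE`, return the raw per-codon contributions
#'   (e.g. a Lys count of 4360 over \{AAA, AAG\} contributes 2180 to each);
#'   if `TRUE` (default), normalise over sense codons to frequencies.
#' @return Named numeric vector over the codons reachable from `map`.
#' @examples
#' m <- decode_map(data.frame(trna = c("Lys", "Lys"), codon = c("AAA", "AAG")))
#' codon_usage_from_trnas(c(Lys = 4360), m, normalize = FALSE)
#' @export
codon_usage_from_trnas <- function(trna_counts, map, normalize = TRUE) {
  stopifnot(is.numeric(trna_counts), !is.null(names(trna_counts)),
            all(trna_counts >= 0))
  map <- decode_map(map)
  missing <- setdiff(names(trna_counts), trna_species(map))
  if (length(missing))
    stop("tRNA species absent from decode map: ", paste(missing, collapse = ", "))
  codons <- sort(unique(map$codon))
  contrib <- stats::setNames(numeric(length(codons)), codons)
  for (t in names(trna_counts)) {
    cogs <- cognate_codons(map, t)
    if (length(cogs))
      contrib[cogs] <- contrib[cogs] + trna_counts[[t]] / length(cogs)
  }
  zero <- names(contrib)[contrib == 0]
  if (length(zero))
    warning("codon(s) with zero usage contribution (unusable): ",
            paste(zero, collapse = ", "))
  if (!normalize) return(contrib)
  if (sum(contrib) <= 0) stop("all codon contributions are zero")
  contrib / sum(contrib)
}

#' Solve the tRNA/codon-usage matching problem
#'
#' Finds nonnegative tRNA abundances whose implied codon usage (equal split
#' of each species over its cognate codons) reproduces a target codon
#' frequency vector. Because several codons are cross-recognised by more
#' than one species the linear system is under-determined and the returned
#' abundances are *one* feasible solution, obtained by nonnegative least
#' squares; the achieved usage and residual are reported so infeasibility is
#' explicit rather than silent.
#'
#' @param codon_freqs named frequency vector over sense codons (normalised
#'   internally).
#' @param map a [decode_map()].
#' @param total_trna total tRNA copy number to distribute.
#' @return A list: `counts` (named integers summing to `total_trna`),
#'   `fractions`, `achieved_usage`, `residual` (max abs deviation of
#'   achieved from target frequency), `feasible` (residual < 1e-6),
#'   `degenerate` (`TRUE` when codon sharing makes the solution non-unique).
#' @export
trnas_from_codon_usage <- function(codon_freqs, map, total_trna = 1e6) {
  stopifnot(is.numeric(codon_freqs), !is.null(names(codon_freqs)),
            all(codon_freqs >= 0), sum(codon_freqs) > 0)
  map <- decode_map(map)
  f <- codon_freqs / sum(codon_freqs)
  species <- trna_species(map)
  codons <- names(f)
  uncov <- codons[!(codons %in% map$codon) & f[codons] > 0]
  if (length(uncov))
    stop("target usage puts weight on codon(s) no tRNA decodes: ",
         paste(uncov, collapse = ", "))
  # A[c, t] = 1/|cognates(t)| if t decodes c; solve A x = f, x >= 0
  A <- matrix(0, length(codons), length(species),
              dimnames = list(codons, species))
  for (t in species) {
    cogs <- intersect(cognate_codons(map, t), codons)
    if (length(cogs))
      A[cogs, t] <- 1 / length(cognate_codons(map, t))
  }
  fit <- pracma::lsqnonneg(A, as.numeric(f))
  x <- stats::setNames(fit$x, species)
  achieved <- as.numeric(A %*% x)
  s <- sum(x)
  if (s <= 0) stop("matching solver returned an all-zero solution")
  x <- x / s
  achieved <- stats::setNames(achieved / sum(achieved), codons)
  residual <- max(abs(achieved - f))
  counts <- round(x * total_trna)
  # non-uniqueness arises when some codon is decoded by >1 species
  degenerate <- any(table(map$codon) > 1L)
  list(counts = stats::setNames(as.integer(counts), species),
       fractions = x,
       achieved_usage = achieved,
       residual = residual,
       feasible = residual < 1e-6,
       degenerate = degenerate)
}

#' Sample the codon sequence of one gene
#'
#' Builds an open reading frame of `length_aa` sense codons drawn i.i.d.
#' from `codon_freqs` (amino-acid identity is deliberately not preserved;
#' only reading-frame length and codon bias matter to translation kinetics),
#' preceded by the start codon and followed by a stop codon.
#'
#' @param length_aa number of sampled sense codons (the encoded protein has
#'   `length_aa + 1` residues counting the initiator).
#' @param codon_freqs named sampling frequencies over sense codons.
#' @param stop_codon `"sample"` (uniform over UAA/UAG/UGA) or a specific
#'   stop codon.
#' @return Character vector of `length_aa + 2` codons (AUG ... stop).
#' @export
sample_gene_codons <- function(length_aa, codon_freqs, stop_codon = "sample") {
  stopifnot(length_aa >= 1)
  stopifnot(all(names(codon_freqs) %in% sense_codons()))
  body <- sample(names(codon_freqs), size = length_aa, replace = TRUE,
                 prob = codon_freqs)
  sc <- if (identical(stop_codon, "sample")) sample(stop_codons(), 1L)
        else match.arg(stop_codon, stop_codons())
  c("AUG", body, sc)
}

#' Sample an mRNA copy number
#'
#' Genes fall into a high (5%), intermediate (35%) or low (60%) expression
#' category; copy numbers are Poisson(lambda = 6.8) for the high category and
#' geometric p(k) = (1 - lambda)^k * lambda for the intermediate
#' (lambda = 0.58) and low (lambda = 0.93) categories. A selected gene is
#' taken to be expressed, so k = 0 draws are resampled (switchable).
#'
#' @param n number of draws.
#' @param category optionally force `"high"`, `"intermediate"` or `"low"`.
#' @param zero_truncate resample k = 0 (default `TRUE`).
#' @return Data frame with columns `category`, `k`.
#' @export
sample_copy_number <- function(n = 1L, category = NULL, zero_truncate = TRUE) {
  cats <- c("high", "intermediate", "low")
  if (is.null(category)) {
    cat_draw <- sample(cats, n, replace = TRUE, prob = c(0.05, 0.35, 0.60))
  } else {
    cat_draw <- rep(match.arg(category, cats), n)
  }
  draw1 <- function(cat) {
    repeat {
      k <- switch(cat,
        high         = stats::rpois(1L, 6.8),
        intermediate = stats::rgeom(1L, 0.58),
        low          = stats::rgeom(1L, 0.93))
      if (!zero_truncate || k >= 1L) return(k)
    }
  }
  data.frame(category = cat_draw,
             k = vapply(cat_draw, draw1, numeric(1L)),
             stringsAsFactors = FALSE)
}

#' Build a transcriptome
#'
#' Genes are drawn one at a time from a gene-length list; each drawn gene
#' receives a sampled codon sequence (bias from `codon_freqs`, length
#' preserved) and a sampled copy number, until the total-nucleotide and/or
#' total-mRNA target is crossed. A length window (in nucleotides, including
#' start and stop codons) restricts the draw for short-mRNA-biased builds.
#'
#' @param gene_lengths data frame with columns `gene_id`, `length_aa`.
#' @param codon_freqs named sampling frequencies over sense codons.
#' @param target_nt,target_n stopping targets: accumulate genes until total
#'   nucleotides >= `target_nt` or total mRNA copies >= `target_n`
#'   (whichever given; both = whichever is crossed first).
#' @param length_window optional `c(min_nt, max_nt)` restriction on mRNA
#'   length.
#' @param replace sample genes with replacement once the list is exhausted
#'   (always without replacement until then).
#' @param stop_codon as in [sample_gene_codons()].
#' @param seed optional integer seed (local to this call).
#' @return A `transcriptome` object: `$genes` (data frame `gene_id`,
#'   `length_aa`, `copies`, `sequence` where `sequence` is the
#'   space-separated codon string), with totals available via
#'   [transcriptome_size()].
#' @export
build_transcriptome <- function(gene_lengths, codon_freqs,
                                target_nt = NULL, target_n = NULL,
                                length_window = NULL, replace = FALSE,
                                stop_codon = "sample", seed = NULL) {
  stopifnot(is.data.frame(gene_lengths),
            all(c("gene_id", "length_aa") %in% names(gene_lengths)),
            nrow(gene_lengths) >= 1, all(gene_lengths$length_aa >= 1))
  if (is.null(target_nt) && is.null(target_n))
    stop("give at least one of target_nt, target_n")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  pool <- gene_lengths
  if (!is.null(length_window)) {
    nt <- 3L * (pool$length_aa + 2L)
    pool <- pool[nt >= length_window[1] & nt <= length_window[2], , drop = FALSE]
    if (!nrow(pool))
      stop("no gene length falls inside the requested window [",
           length_window[1], ", ", length_window[2], "] nt")
  }
  avail <- seq_len(nrow(pool))
  ids <- character(0); lens <- integer(0); copies <- integer(0)
  seqs <- character(0)
  tot_nt <- 0; tot_n <- 0L
  crossed <- function() {
    (!is.null(target_nt) && tot_nt >= target_nt) ||
      (!is.null(target_n) && tot_n >= target_n)
  }
  while (!crossed()) {
    if (!length(avail)) {
      if (!replace)
        stop("gene list exhausted before reaching the target; ",
             "set replace = TRUE to re-draw genes")
      avail <- seq_len(nrow(pool))
    }
    pick <- avail[sample.int(length(avail), 1L)]
    avail <- setdiff(avail, pick)
    len <- pool$length_aa[pick]
    k <- sample_copy_number(1L)$k
    ids <- c(ids, pool$gene_id[pick])
    lens <- c(lens, len)
    copies <- c(copies, as.integer(k))
    seqs <- c(seqs, paste(sample_gene_codons(len, codon_freqs, stop_codon),
                          collapse = " "))
    tot_n <- tot_n + as.integer(k)
    tot_nt <- tot_nt + k * 3L * (len + 2L)
  }
  transcriptome(data.frame(gene_id = ids, length_aa = lens, copies = copies,
                           sequence = seqs, stringsAsFactors = FALSE))
}

#' Transcriptome objects
#'
#' @param genes data frame with columns `gene_id`, `length_aa`, `copies`,
#'   `sequence` (space-separated codons including start and stop).
#' @return A validated `transcriptome`.
#' @export
transcriptome <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "length_aa", "copies", "sequence") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in transcriptome")
  if (any(genes$copies < 1)) stop("every gene must have at least one mRNA copy")
  cl <- codon_list(genes)
  for (i in seq_along(cl)) {
    cods <- cl[[i]]
    if (length(cods) != genes$length_aa[i] + 2L)
      stop("gene ", genes$gene_id[i], ": sequence length disagrees with length_aa")
    if (cods[1] != "AUG")
      stop("gene ", genes$gene_id[i], " does not start with AUG")
    if (!(cods[length(cods)] %in% stop_codons()))
      stop("gene ", genes$gene_id[i], " does not end with a stop codon")
    if (any(cods[-length(cods)] %in% stop_codons()))
      stop("gene ", genes$gene_id[i], " contains an internal stop codon")
  }
  structure(list(genes = genes), class = "transcriptome")
}

codon_list <- function(genes) strsplit(genes$sequence, " ", fixed = TRUE)

#' @describeIn transcriptome totals: number of mRNAs `n`, total nucleotides
#'   `n_nt` (copies included), number of distinct genes.
#' @param tx a `transcriptome`.
#' @export
transcriptome_size <- function(tx) {
  g <- tx$genes
  list(n = sum(g$copies),
       n_nt = sum(g$copies * 3L * (g$length_aa + 2L)),
       n_genes = nrow(g))
}

#' @export
print.transcriptome <- function(x, ...) {
  s <- transcriptome_size(x)
  cat("Transcriptome:", s$n_genes, "genes,", s$n, "mRNAs,", s$n_nt,
      "nucleotides\n")
  invisible(x)
}

#' Rebuild a transcriptome with a different codon bias
#'
#' Produces a mismatch companion of `tx`: identical genes, reading-frame
#' lengths and copy numbers, but codons re-sampled from `codon_freqs`. Used
#' to study tRNA-abundance/codon-bias mismatch with everything else held
#' fixed.
#'
#' @param tx a `transcriptome`.
#' @param codon_freqs new sampling frequencies.
#' @inheritParams build_transcriptome
#' @export
rebuild_with_usage <- function(tx, codon_freqs, stop_codon = "sample",
                               seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  g <- tx$genes
  g$sequence <- vapply(g$length_aa, function(len)
    paste(sample_gene_codons(len, codon_freqs, stop_codon), collapse = " "),
    character(1L))
  transcriptome(g)
}

#' Empirical codon usage of a transcriptome
#'
#' Copy-number-weighted frequency of each sense codon over all ORFs
#' (start and stop codons excluded).
#'
#' @param tx a `transcriptome`.
#' @return Named frequency vector over the codons present.
#' @export
transcriptome_codon_usage <- function(tx) {
  cl <- codon_list(tx$genes)
  all_body <- unlist(mapply(function(cods, k) {
    rep(cods[2:(length(cods) - 1L)], k)
  }, cl, tx$genes$copies, SIMPLIFY = FALSE))
  tt <- table(all_body)
  out <- as.numeric(tt) / sum(tt)
  stats::setNames(out, names(tt))
}

#' Read and write transcriptomes (FASTA + copy-number TSV)
#'
#' Unique gene sequences go to an RNA FASTA (one record per gene); copy
#' numbers go to a two-column TSV (`gene_id`, `copies`).
#'
#' @param tx a `transcriptome`.
#' @param fasta,copies_tsv output paths.
#' @export
write_transcriptome <- function(tx, fasta, copies_tsv) {
  g <- tx$genes
  seqs <- Biostrings::RNAStringSet(gsub(" ", "", g$sequence, fixed = TRUE))
  names(seqs) <- g$gene_id
  Biostrings::writeXStringSet(seqs, fasta)
  utils::write.table(data.frame(gene_id = g$gene_id, copies = g$copies),
                     copies_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tx)
}

#' @rdname write_transcriptome
#' @export
read_transcriptome <- function(fasta, copies_tsv) {
  seqs <- Biostrings::readRNAStringSet(fasta)
  ks <- utils::read.delim(copies_tsv, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "copies") %in% names(ks)))
  sq <- as.character(seqs)
  if (any(nchar(sq) %% 3L != 0L))
    stop("FASTA sequence length is not a multiple of 3")
  ord <- match(names(seqs), ks$gene_id)
  if (anyNA(ord)) stop("copy-number table is missing genes present in FASTA")
  split_codons <- function(s)
    paste(substring(s, seq(1, nchar(s), 3L), seq(3, nchar(s), 3L)),
          collapse = " ")
  transcriptome(data.frame(
    gene_id = names(seqs),
    length_aa = as.integer(nchar(sq) / 3L) - 2L,
    copies = as.integer(ks$copies[ord]),
    sequence = vapply(sq, split_codons, character(1L), USE.NAMES = FALSE),
    stringsAsFactors = FALSE))
}
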