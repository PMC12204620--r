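# Sequence-based differentiation for haploid (mitochondrial) data:
# alignment input, SNP extraction, pairwise distances, and Phi-ST via
# two-level AMOVA on squared pairwise distances.

#' Read an aligned FASTA with a population-label sidecar
#'
#' @param path aligned FASTA file.
#' @param meta_path optional CSV sidecar with columns `id`, `population`
#'   and optionally `latitude`, `longitude`.  Without a sidecar, labels
#'   are parsed from headers of the form `id|population` when present.
#' @return object of class `alignment`: `sequences` (lowercase character
#'   matrix, rows = sequences), `labels`, `coords` (or NULL).
#' @export
read_alignment <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop_fmt("read_alignment: no such file '%s'",
                                   path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop_fmt("read_alignment: empty file '%s'", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1) {
    off <- names(dna)[lens != lens[1]][1]
    stop_fmt("read_alignment: ragged alignment ('%s' has %d sites, %s",
             off, lens[names(dna) == off][1],
             sprintf("expected %d)", lens[1]))
  }
  seqs <- tolower(as.character(as.matrix(dna)))
  ids <- rownames(seqs)
  labels <- NULL; coords <- NULL
  if (!is.null(meta_path)) {
    meta <- read.csv(meta_path, stringsAsFactors = FALSE)
    if (!all(c("id", "population") %in% names(meta)))
      stop_fmt("read_alignment: sidecar needs 'id' and 'population'")
    m <- match(ids, meta$id)
    if (anyNA(m))
      stop_fmt("read_alignment: sidecar missing id(s): %s",
               paste(head(ids[is.na(m)], 3), collapse = ", "))
    labels <- meta$population[m]
    if (all(c("latitude", "longitude") %in% names(meta)))
      coords <- data.frame(id = ids, population = labels,
                           latitude = meta$latitude[m],
                           longitude = meta$longitude[m])
  } else if (all(grepl("\\|", ids))) {
    labels <- sub("^.*\\|", "", ids)
  }
  structure(list(sequences = seqs, labels = labels, coords = coords),
            class = "alignment")
}

#' Extract a haploid SNP matrix from an alignment
#'
#' Keeps polymorphic sites only (two or more distinct unambiguous bases),
#' coding the major allele 0 and the minor 1; gaps and ambiguity codes
#' become missing.  Major-allele ties break alphabetically.
#'
#' @param aln an `alignment`.
#' @return samples x sites numeric matrix (possibly zero columns, with a
#'   warning).
#' @export
snp_matrix <- function(aln) {
  seqs <- aln$sequences
  bases <- c("a", "c", "g", "t")
  cols <- list()
  for (s in seq_len(ncol(seqs))) {
    x <- seqs[, s]
    valid <- x %in% bases
    tab <- sort(table(x[valid]), decreasing = TRUE)
    if (length(tab) < 2) next
    major <- names(tab)[1]              # ties: table is alphabetical, so
    col <- ifelse(valid, as.numeric(x != major), NA)
    cols[[length(cols) + 1]] <- col
  }
  if (length(cols) == 0) {
    warning("snp_matrix: no polymorphic sites", call. = FALSE)
    return(matrix(numeric(0), nrow(seqs), 0))
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(seqs)
  out
}

#' Pairwise sequence distance matrix
#'
#' Mismatch proportion over ungapped shared sites; the default reports its
#' square root (the convention of the classical alignment-distance
#' implementation), `mode = "p_distance"` the raw proportion.
#'
#' @param aln an `alignment`.
#' @param mode `"sqrt_mismatch"` (default) or `"p_distance"`.
#' @return symmetric distance matrix with a zero diagonal.
#' @export
seq_distance_matrix <- function(aln, mode = c("sqrt_mismatch",
                                              "p_distance")) {
  mode <- match.arg(mode)
  seqs <- aln$sequences
  bases <- c("a", "c", "g", "t")
  n <- nrow(seqs)
  ok <- matrix(seqs %in% bases, n, ncol(seqs))
  d <- matrix(0, n, n, dimnames = list(rownames(seqs), rownames(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    shared <- ok[i, ] & ok[j, ]
    if (!any(shared))
      stop_fmt("seq_distance_matrix: no shared ungapped sites for %s",
               sprintf("pair (%d, %d)", i, j))
    p <- mean(seqs[i, shared] != seqs[j, shared])
    d[i, j] <- d[j, i] <- if (mode == "sqrt_mismatch") sqrt(p) else p
  }
  d
}

#' Two-level AMOVA and Phi-ST
#'
#' Partitions molecular variance among versus within populations from
#' squared pairwise distances, with the standard n0 coefficient for
#' unequal sample sizes.  Phi-ST is `sigma2_among / (sigma2_among +
#' sigma2_within)`.  Negative variance components are reported raw but
#' floored at zero for the percentage split.
#'
#' @param x an `alignment` or a pairwise distance matrix whose squares
#'   enter the sums of squares.  For an alignment the squared distance is
#'   the count of pairwise nucleotide differences (the standard molecular
#'   distance), i.e. `d = sqrt(differences)`.
#' @param labels population label per sequence (taken from the alignment
#'   when omitted).
#' @return object of class `amova_result`: `sigma_among`, `sigma_within`,
#'   `phi_st`, `pct_between`, `pct_within`, `ss_among`, `ss_within`,
#'   `df_among`, `df_within`, `n0`.
#' @export
amova_two_level <- function(x, labels = NULL) {
  if (inherits(x, "alignment")) {
    if (is.null(labels)) labels <- x$labels
    d <- amova_distance(x)
  } else {
    d <- as.matrix(x)
  }
  if (is.null(labels)) stop_fmt("amova_two_level: population labels needed")
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop_fmt("amova_two_level: need at least 2 populations")
  sizes <- table(labels)
  if (any(sizes < 2))
    warning("amova_two_level: population(s) with a single sequence; the ",
            "within component is degenerate", call. = FALSE)
  n <- length(labels)
  k <- nlevels(labels)
  d2 <- d^2

  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (lv in levels(labels)) {
    rows <- which(labels == lv)
    if (length(rows) > 1) {
      sub <- d2[rows, rows]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(rows)
    }
  }
  ss_among <- ss_total - ss_within
  df_among <- k - 1
  df_within <- n - k
  ms_among <- ss_among / df_among
  ms_within <- if (df_within > 0) ss_within / df_within else NA_real_
  n0 <- (n - sum(sizes^2) / n) / (k - 1)
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  tot <- max(sigma_among, 0) + max(sigma_within, 0)
  phi <- if (sigma_among + sigma_within > 0)
    sigma_among / (sigma_among + sigma_within) else NA_real_
  structure(list(sigma_among = sigma_among, sigma_within = sigma_within,
                 phi_st = phi,
                 pct_between = if (tot > 0) 100 * max(sigma_among, 0) /
                   tot else NA_real_,
                 pct_within = if (tot > 0) 100 * max(sigma_within, 0) /
                   tot else NA_real_,
                 ss_among = ss_among, ss_within = ss_within,
                 df_among = df_among, df_within = df_within, n0 = n0),
            class = "amova_result")
}

# sqrt of the pairwise-difference count, so that the squared distances in
# the AMOVA sums of squares are the nucleotide difference counts
amova_distance <- function(aln) {
  sqrt(seq_distance_matrix(aln, mode = "p_distance") *
         ncol(aln$sequences))
}

#' Phi-ST by label permutation
#'
#' @param x distance matrix or alignment (see [amova_two_level()]).
#' @param labels population labels.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list: `phi_st`, `p` (upper tail, add-one correction).
#' @export
phi_st_permutation_test <- function(x, labels, n_perm = 999, seed = 1) {
  obs <- amova_two_level(x, labels)$phi_st
  d <- if (inherits(x, "alignment")) amova_distance(x) else as.matrix(x)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (amova_two_level(d, sample(labels))$phi_st >= obs)
      exceed <- exceed + 1L
  }
  list(phi_st = obs, p = (1 + exceed) / (n_perm + 1))
}

#' Pairwise Phi-ST table over all population pairs
#'
#' @param x an `alignment` or distance matrix.
#' @param labels population labels.
#' @return data frame: `pop1`, `pop2`, `phi_st`, `pct_between`.
#' @export
pairwise_phi_st <- function(x, labels = NULL) {
  if (inherits(x, "alignment")) {
    if (is.null(labels)) labels <- x$labels
    d <- amova_distance(x)
  } else d <- as.matrix(x)
  labels <- factor(labels)
  lv <- levels(labels)
  if (length(lv) < 2) stop_fmt("pairwise_phi_st: need >= 2 populations")
  out <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (j > i) {
    rows <- which(labels %in% lv[c(i, j)])
    a <- amova_two_level(d[rows, rows], droplevels(labels[rows]))
    out[[length(out) + 1]] <- data.frame(pop1 = lv[i], pop2 = lv[j],
                                         phi_st = a$phi_st,
                                         pct_between = a$pct_between)
  }
  do.call(rbind, out)
}
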