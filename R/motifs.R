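AA_ALPHABET20 <- "ACDEFGHIKLMNPQRSTVWY"

#' Construct a conserved-cysteine spacing pattern
#'
#' Soluble olfactory proteins (OBPs, CSPs) are classified by the number of
#' conserved cysteines and the spacings between them. A pattern is an
#' ordered list of gap windows: `gaps[i] = c(min, max)` constrains the
#' number of residues strictly between conserved cysteine i and cysteine
#' i + 1 (so a written spacing of "Cys-X30-Cys" means the positions differ
#' by 31). A pattern with g gap windows involves g + 1 cysteines.
#'
#' @param name class label, e.g. `"minus_c_obp"`.
#' @param gaps list of length-2 integer vectors `c(min_gap, max_gap)`, or a
#'   2-column matrix (one row per gap).
#' @return an object of class `cys_pattern`: list with `name`, `gaps`
#'   (2-column matrix) and `cys_count`.
#' @export
cys_pattern <- function(name, gaps) {
  if (is.list(gaps)) gaps <- do.call(rbind, gaps)
  gaps <- matrix(as.integer(gaps), ncol = 2)
  colnames(gaps) <- c("min", "max")
  if (any(gaps < 0)) stop("gap bounds must be >= 0")
  if (any(gaps[, 1] > gaps[, 2])) stop("min_gap must be <= max_gap")
  structure(list(name = name, gaps = gaps,
                 cys_count = nrow(gaps) + 1L),
            class = "cys_pattern")
}

#' @export
print.cys_pattern <- function(x, ...) {
  w <- apply(x$gaps, 1, function(g)
    if (g[1] == g[2]) as.character(g[1]) else paste0(g[1], "-", g[2]))
  cat(sprintf("%s (%d Cys): Cys-%s-Cys\n", x$name, x$cys_count,
              paste0("X", w, collapse = "-Cys-")))
  invisible(x)
}

#' Shipped cysteine-spacing patterns for OBP/CSP classification
#'
#' Four patterns: minus-C OBPs (4 conserved cysteines), classic OBPs (6),
#' plus-C OBPs (8) and CSPs (4 with short spacings). Patterns whose
#' published spacing is a range are shipped as that range; single observed
#' spacings get a symmetric tolerance, because a spacing measured on one
#' species' sequences is not a family-wide constraint. By default the
#' tolerance is +/-2 residues for gaps longer than 10 and 0 for short gaps
#' (short spacings are structurally rigid).
#'
#' @param tolerance half-width added to single-valued gaps longer than
#'   `tight_below` (default 2).
#' @param tight_below gaps of this many residues or fewer get no tolerance
#'   (default 10).
#' @return named list of [cys_pattern()] objects: `minus_c_obp`,
#'   `classic_obp`, `plus_c_obp`, `csp`.
#' @export
default_cys_patterns <- function(tolerance = 2, tight_below = 10) {
  widen <- function(g) {
    t(vapply(g, function(x) {
      if (length(x) == 2) return(as.numeric(x))
      tol <- if (x > tight_below) tolerance else 0
      c(max(0, x - tol), x + tol)
    }, numeric(2)))
  }
  list(
    minus_c_obp = cys_pattern("minus_c_obp",
                              list(c(28, 32), c(37, 39), c(16, 23))),
    classic_obp = cys_pattern("classic_obp",
                              widen(list(27, 3, 29, 9, 8))),
    plus_c_obp = cys_pattern("plus_c_obp",
                             widen(list(35, 3, 43, 13, 9, 8, 10))),
    csp = cys_pattern("csp", widen(list(c(6, 8), 18, 2)))
  )
}

check_residues <- function(seq) {
  ok <- strsplit(paste0(AA_ALPHABET20, "X"), "")[[1]]
  res <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(res), ok)
  if (length(bad) > 0)
    stop("invalid residue character(s): ", paste(bad, collapse = ", "))
  res
}

#' Find all matches of a cysteine-spacing pattern in a protein sequence
#'
#' Depth-first search over the sequence's cysteine positions for every
#' increasing subsequence whose consecutive gaps (residues strictly between
#' the two cysteines) fall inside the pattern's windows. Non-matched
#' cysteines are allowed inside gaps by default (the patterns describe
#' conserved cysteines; family members may carry extras); `strict = TRUE`
#' forbids them, reading "X = any residue except Cys" literally.
#'
#' @param seq amino-acid string over the 20-letter alphabet (plus `X`,
#'   which never matches Cys).
#' @param pattern a [cys_pattern()].
#' @param mature_start 1-based position where the analyzed region starts
#'   (use this to skip a signal peptide); positions in the result are
#'   relative to this region.
#' @param strict forbid intervening cysteines inside gaps (default FALSE).
#' @return list of matches; each is a list with `pattern` (name),
#'   `positions` (1-based cysteine positions within the analyzed region)
#'   and `offset` (`mature_start - 1`). Empty list when nothing matches.
#' @examples
#' p <- default_cys_patterns()$csp
#' s <- paste0(strrep("A", 4), "C", strrep("A", 7), "C", strrep("A", 18),
#'             "C", strrep("A", 2), "C", strrep("A", 5))
#' length(find_matches(s, p))  # 1
#' @export
find_matches <- function(seq, pattern, mature_start = 1, strict = FALSE) {
  stopifnot(inherits(pattern, "cys_pattern"))
  res <- check_residues(seq)
  if (mature_start < 1 || mature_start > length(res))
    stop("`mature_start` outside the sequence")
  res <- res[mature_start:length(res)]
  cys <- which(res == "C")
  matches <- list()
  gaps <- pattern$gaps
  n_need <- pattern$cys_count

  extend <- function(chosen) {
    depth <- length(chosen)
    if (depth == n_need) {
      matches[[length(matches) + 1L]] <<- list(
        pattern = pattern$name,
        positions = chosen,
        offset = mature_start - 1L)
      return(invisible(NULL))
    }
    lo <- chosen[depth] + gaps[depth, 1] + 1
    hi <- chosen[depth] + gaps[depth, 2] + 1
    for (p in cys[cys >= lo & cys <= hi]) {
      if (strict && any(cys > chosen[depth] & cys < p)) next
      extend(c(chosen, p))
    }
  }
  for (start in cys) extend(start)
  matches
}

#' Classify a protein sequence by cysteine spacing
#'
#' Tries every pattern; among patterns with at least one match, the one
#' involving the most conserved cysteines wins (plus-C over classic over
#' the 4-cysteine classes). If several patterns with the same cysteine
#' count match, all their labels are returned (an ambiguity the caller must
#' resolve, e.g. a sequence satisfying both the minus-C OBP and CSP
#' windows). With no match the label is `"unclassified"`.
#'
#' @inheritParams find_matches
#' @param patterns named list of [cys_pattern()] objects (default
#'   [default_cys_patterns()]).
#' @return character vector of winning class label(s), or
#'   `"unclassified"`.
#' @export
classify_sequence <- function(seq, patterns = default_cys_patterns(),
                              mature_start = 1, strict = FALSE) {
  if (length(patterns) == 0) return("unclassified")
  hits <- Filter(function(p)
    length(find_matches(seq, p, mature_start, strict)) > 0, patterns)
  if (length(hits) == 0) return("unclassified")
  counts <- vapply(hits, function(p) p$cys_count, integer(1))
  labels <- vapply(hits[counts == max(counts)], function(p) p$name,
                   character(1))
  unname(labels)
}

#' Classify all sequences of a FASTA file
#'
#' @param sequences named character vector as returned by [read_fasta()],
#'   or a path to a FASTA file.
#' @inheritParams classify_sequence
#' @return data.frame with columns `id`, `label` (ambiguous labels joined
#'   with `;`), `n_matches` (for the winning pattern(s)).
#' @export
classify_fasta <- function(sequences, patterns = default_cys_patterns(),
                           strict = FALSE) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences))
    sequences <- read_fasta(sequences)
  names(patterns) <- vapply(patterns, `[[`, character(1), "name")
  rows <- lapply(seq_along(sequences), function(i) {
    labels <- classify_sequence(sequences[[i]], patterns, strict = strict)
    nm <- if (identical(labels, "unclassified")) 0L else
      sum(vapply(patterns[labels], function(p)
        length(find_matches(sequences[[i]], p, strict = strict)),
        integer(1)))
    data.frame(id = names(sequences)[i],
               label = paste(labels, collapse = ";"),
               n_matches = nm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over Biostrings; sequence ids are the first whitespace
#' token of each header.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @return named character vector of sequences, file order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no sequences in FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
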