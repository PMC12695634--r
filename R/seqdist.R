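#' @importFrom utils data
NULL

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

identity_matrix <- function(match = 1, mismatch = -1) {
  letters <- c(AA20, "X")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  # X is scored as a mismatch against everything, including itself
  m["X", "X"] <- mismatch
  m
}

resolve_substitution <- function(substitution, match, mismatch) {
  if (is.matrix(substitution)) return(substitution)
  switch(match.arg(substitution, c("blosum62", "identity")),
         blosum62 = blosum62_matrix(),
         identity = identity_matrix(match, mismatch))
}

check_residues <- function(chars, sub) {
  bad <- setdiff(unique(chars), rownames(sub))
  if (length(bad))
    stop("illegal residue characters: ", paste(bad, collapse = ", "))
}

#' Global pairwise protein alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under affine gap penalties (Gotoh
#' three-state dynamic programming): the first residue of a gap run scores
#' `gap_open`, each further residue `gap_extend`. Traceback tie-breaking is
#' fixed and documented — prefer the substitution (diagonal) state, then a
#' gap in the second sequence (up), then a gap in the first (left) — so
#' alignments are bit-reproducible. The sequence distance is
#' `D = 1 - matches / alignment_length`, in `[0, 1]`.
#'
#' @param seq_a,seq_b amino-acid sequences (single strings over the 20-letter
#'   alphabet; `X` permitted and scored as a mismatch).
#' @param substitution `"blosum62"` (default), `"identity"`, or a named
#'   substitution matrix.
#' @param match,mismatch scores used by the identity scheme.
#' @param gap_open score of the first residue in a gap (default -10).
#' @param gap_extend score of each gap extension (default -1).
#' @return object of class `alignment_result`: `aligned_a`, `aligned_b`
#'   (gapped strings), `score`, `matches`, `alignment_length`, `D`.
#' @export
needleman_wunsch <- function(seq_a, seq_b, substitution = "blosum62",
                             match = 1, mismatch = -1,
                             gap_open = -10, gap_extend = -1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be nonempty")
  sub <- resolve_substitution(substitution, match, mismatch)
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  check_residues(a, sub); check_residues(b, sub)
  n <- length(a); m <- length(b)
  go <- gap_open; ge <- gap_extend
  NEG <- -1e18

  # state matrices over (0..n) x (0..m): S substitution, U gap in b (up),
  # L gap in a (left)
  S <- matrix(NEG, n + 1L, m + 1L)
  U <- matrix(NEG, n + 1L, m + 1L)
  L <- matrix(NEG, n + 1L, m + 1L)
  S[1L, 1L] <- 0
  if (n >= 1L) U[2L:(n + 1L), 1L] <- go + (seq_len(n) - 1L) * ge
  if (m >= 1L) L[1L, 2L:(m + 1L)] <- go + (seq_len(m) - 1L) * ge

  js <- seq_len(m)
  for (i in seq_len(n)) {
    ip <- i; ic <- i + 1L
    sub_row <- sub[a[i], b]
    best_prev <- pmax(S[ip, js], U[ip, js], L[ip, js])       # (i-1, j-1)
    S[ic, js + 1L] <- sub_row + best_prev
    U[ic, js + 1L] <- pmax(S[ip, js + 1L] + go,
                           U[ip, js + 1L] + ge,
                           L[ip, js + 1L] + go)
    # L[ic, j] = max(base[j], L[ic, j-1] + ge): running-max recurrence
    base <- pmax(S[ic, js], U[ic, js]) + go
    base[1L] <- max(base[1L], L[ic, 1L] + ge)
    L[ic, js + 1L] <- cummax(base - js * ge) + js * ge
    S[ic, 1L] <- NEG
  }

  # traceback with fixed priority: diagonal (S) > up (U) > left (L)
  pick_state <- function(i, j) {
    vals <- c(S = S[i + 1L, j + 1L], U = U[i + 1L, j + 1L], L = L[i + 1L, j + 1L])
    names(vals)[which.max(vals + c(2e-9, 1e-9, 0))]
  }
  out_a <- character(0); out_b <- character(0)
  i <- n; j <- m
  state <- pick_state(i, j)
  score <- max(S[n + 1L, m + 1L], U[n + 1L, m + 1L], L[n + 1L, m + 1L])
  tol <- 1e-9
  while (i > 0L || j > 0L) {
    if (state == "S") {
      out_a <- c(a[i], out_a); out_b <- c(b[j], out_b)
      target <- S[i + 1L, j + 1L] - sub[a[i], b[j]]
      i <- i - 1L; j <- j - 1L
      state <- if (abs(S[i + 1L, j + 1L] - target) < tol) "S"
      else if (abs(U[i + 1L, j + 1L] - target) < tol) "U" else "L"
    } else if (state == "U") {
      out_a <- c(a[i], out_a); out_b <- c("-", out_b)
      val <- U[i + 1L, j + 1L]
      i <- i - 1L
      state <- if (abs(S[i + 1L, j + 1L] + go - val) < tol) "S"
      else if (abs(U[i + 1L, j + 1L] + ge - val) < tol) "U" else "L"
    } else {
      out_a <- c("-", out_a); out_b <- c(b[j], out_b)
      val <- L[i + 1L, j + 1L]
      j <- j - 1L
      state <- if (abs(S[i + 1L, j + 1L] + go - val) < tol) "S"
      else if (abs(U[i + 1L, j + 1L] + go - val) < tol) "U" else "L"
    }
  }
  alen <- length(out_a)
  matches <- sum(out_a == out_b & out_a != "-")
  structure(list(aligned_a = paste(out_a, collapse = ""),
                 aligned_b = paste(out_b, collapse = ""),
                 score = score, matches = matches,
                 alignment_length = alen,
                 D = 1 - matches / alen),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %.1f | %d/%d identities | D = %.3f\n%s\n%s\n",
              x$score, x$matches, x$alignment_length, x$D,
              x$aligned_a, x$aligned_b))
  invisible(x)
}

#' Alignment distance of every variant to a parent sequence
#'
#' Aligns each variant globally against the parent with
#' [needleman_wunsch()] and tabulates the normalized sequence distance
#' `D = 1 - identities / alignment_length`.
#'
#' @param variants a [make_variant_sequences()] result, a named character
#'   vector of sequences, or a FASTA file path.
#' @param parent parent sequence; taken from a `variant_set` if omitted.
#' @param ... passed to [needleman_wunsch()].
#' @return data.frame with `variant_id`, `score`, `matches`,
#'   `alignment_length`, `D`.
#' @export
distance_to_parent <- function(variants, parent = NULL, ...) {
  if (inherits(variants, "variant_set")) {
    if (is.null(parent)) parent <- variants$parent
    variants <- variants$sequences
  } else if (is.character(variants) && length(variants) == 1L &&
             file.exists(variants)) {
    variants <- read_fasta_sequences(variants)
  }
  if (is.null(parent) || !nzchar(parent)) stop("parent sequence required")
  if (length(variants) == 0L)
    return(data.frame(variant_id = character(0), score = numeric(0),
                      matches = integer(0), alignment_length = integer(0),
                      D = numeric(0)))
  rows <- lapply(seq_along(variants), function(i) {
    al <- needleman_wunsch(variants[[i]], parent, ...)
    data.frame(variant_id = names(variants)[i] %||% paste0("var", i),
               score = al$score, matches = al$matches,
               alignment_length = al$alignment_length, D = al$D,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sequence-distance summary per acoustic-map region
#'
#' Mean, s.e.m. and n of the alignment distance `D` within each region, plus
#' unpaired two-sample Welch comparisons between all region pairs
#' (uncorrected). Regions with fewer than two members are excluded with a
#' warning.
#'
#' @param D numeric distances (or the data.frame from
#'   [distance_to_parent()], whose `D` column is used).
#' @param regions character region labels, one per distance.
#' @return list with `summary` (region, n, mean, sem) and `tests`
#'   (region_a, region_b, p_value).
#' @export
region_distance_summary <- function(D, regions) {
  if (is.data.frame(D)) D <- D$D
  if (length(regions) == 0L || length(D) != length(regions))
    stop("need one region label per distance")
  tab <- table(regions)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("excluding regions with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !(regions %in% small)
    D <- D[keep]; regions <- regions[keep]
  }
  groups <- split(D, regions)
  if (length(groups) < 2L) stop("need at least 2 regions with >= 2 members")
  summary_df <- data.frame(
    region = names(groups),
    n = vapply(groups, length, 0L),
    mean = vapply(groups, mean, 0),
    sem = vapply(groups, function(v) sd(v) / sqrt(length(v)), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  combos <- utils::combn(names(groups), 2L)
  tests <- data.frame(
    region_a = combos[1L, ], region_b = combos[2L, ],
    p_value = apply(combos, 2L, function(pair) {
      tryCatch(t.test(groups[[pair[1L]]], groups[[pair[2L]]])$p.value,
               error = function(e) NA_real_)
    }),
    stringsAsFactors = FALSE)
  list(summary = summary_df, tests = tests)
}
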