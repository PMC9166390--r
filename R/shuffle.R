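#' Overlapping dinucleotide counts
#'
#' @param seq A single DNA sequence over `{A,C,G,T}`.
#' @return Named integer vector of the 16 dinucleotide counts (AA, AC, ...,
#'   TT).
#' @export
dinucleotide_counts <- function(seq) {
  seq <- as_dna(seq)
  stopifnot(length(seq) == 1L)
  if (grepl("N", seq)) stop("dinucleotide counts are defined over {A,C,G,T} only")
  v <- strsplit(seq, "")[[1]]
  keys <- paste0(rep(BASES, each = 4), BASES)
  out <- integer(16)
  names(out) <- keys
  if (length(v) >= 2) {
    di <- paste0(v[-length(v)], v[-1])
    tab <- table(di)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

# One random Euler path over the dinucleotide transition multigraph
# (Altschul-Erickson): for every vertex except the terminal one, sample a
# final outgoing edge; accept the sample when following those final edges
# from every used vertex reaches the terminal vertex (the chosen edges then
# form an arborescence), order the remaining out-edges uniformly with the
# final edge last, and walk the graph greedily.
shuffle_euler <- function(codes) {
  n <- length(codes)
  first <- codes[1L]
  last <- codes[n]
  out_edges <- vector("list", 4L)
  for (b in 1:4) out_edges[[b]] <- codes[which(codes[-n] == b) + 1L]
  used <- which(vapply(out_edges, length, 1L) > 0L)
  non_terminal <- setdiff(used, last)

  repeat {
    final_edge <- integer(4)
    for (b in non_terminal) {
      e <- out_edges[[b]]
      final_edge[b] <- e[sample.int(length(e), 1L)]
    }
    ok <- TRUE
    for (b in non_terminal) {
      v <- b
      steps <- 0L
      while (v != last) {
        if (v == 0L || final_edge[v] == 0L || steps > 4L) { ok <- FALSE; break }
        v <- final_edge[v]
        steps <- steps + 1L
      }
      if (!ok) break
    }
    if (ok) break
  }

  ordered <- vector("list", 4L)
  for (b in used) {
    e <- out_edges[[b]]
    if (b %in% non_terminal) {
      i <- which(e == final_edge[b])[1L]
      rest <- e[-i]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      ordered[[b]] <- c(rest, final_edge[b])
    } else {
      ordered[[b]] <- if (length(e) > 1L) e[sample.int(length(e))] else e
    }
  }

  res <- integer(n)
  res[1L] <- first
  ptr <- integer(4)
  v <- first
  for (i in 2:n) {
    ptr[v] <- ptr[v] + 1L
    nxt <- ordered[[v]][ptr[v]]
    res[i] <- nxt
    v <- nxt
  }
  res
}

#' Dinucleotide-count-preserving shuffle
#'
#' Randomly rearranges a sequence while conserving its exact multiset of
#' overlapping dinucleotides (hence also length, mononucleotide counts and
#' the first and last base), via a random Euler path on the base-transition
#' multigraph (Altschul-Erickson construction). Used to build negative sets
#' that differ from the positives in motif content but not in dinucleotide
#' composition.
#'
#' @param seq A single sequence over `{A,C,G,T}`, length >= 2.
#' @param seed Optional integer seed for a reproducible draw; `NULL` uses the
#'   current RNG stream.
#' @return The shuffled sequence.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  seq <- as_dna(seq)
  stopifnot(length(seq) == 1L)
  if (nchar(seq) < 2L) stop("sequence must have length >= 2")
  if (grepl("N", seq)) stop("dinucleotide shuffle requires a pure {A,C,G,T} sequence")
  codes <- as.integer(encode_reads(seq)[1L, ])
  res <- local_seed(seed, shuffle_euler(codes))
  paste(BASES[res], collapse = "")
}

#' Build a shuffled negative set
#'
#' One dinucleotide-preserving shuffle per positive read, in corresponding
#' order, giving equally sized positive and negative sets.
#'
#' @param reads Character vector of positive reads (pure `{A,C,G,T}`).
#' @param seed Optional integer seed.
#' @return Character vector of negatives, named `shuf_<original id>` when
#'   `reads` is named.
#' @export
build_negative_set <- function(reads, seed = NULL) {
  if (!length(reads)) return(character(0))
  local_seed(seed, {
    out <- vapply(seq_along(reads), function(i) {
      tryCatch(dinucleotide_shuffle(reads[[i]]),
               error = function(e) stop(sprintf("read %d: %s", i, conditionMessage(e)),
                                        call. = FALSE))
    }, character(1))
    if (!is.null(names(reads))) names(out) <- paste0("shuf_", names(reads))
    out
  })
}
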