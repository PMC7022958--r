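# run code under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specification of a synthetic homologous family
#'
#' Describes a star-phylogeny family: `n_members` sequences derived
#' independently from one ancestor by point substitutions (and optional
#' indels) until each member's global-alignment identity to the ancestor
#' falls inside `target_identity +- identity_tolerance`.
#'
#' @param ancestor_length Ancestor length (>= 10 residues).
#' @param n_members Number of family members.
#' @param target_identity Target percent identity to the ancestor, in
#'   [5, 100].
#' @param identity_tolerance Acceptance half-band in percent (> 0).
#' @param indel_rate Per-site indel probability per mutation batch, in
#'   [0, 0.1].
#' @param molecule Molecule type.
#' @param seed Master seed; all member seeds derive from it.
#' @return A `family_spec` list.
#' @export
family_spec <- function(ancestor_length = 150L, n_members = 20L,
                        target_identity = 25, identity_tolerance = 3,
                        indel_rate = 0.01,
                        molecule = c("protein", "dna", "rna"),
                        seed = 1L) {
  molecule <- match.arg(molecule)
  stopifnot(ancestor_length >= 10, n_members >= 1,
            target_identity >= 5, target_identity <= 100,
            identity_tolerance > 0 || target_identity == 100,
            indel_rate >= 0, indel_rate <= 0.1)
  structure(list(ancestor_length = as.integer(ancestor_length),
                 n_members = as.integer(n_members),
                 target_identity = target_identity,
                 identity_tolerance = identity_tolerance,
                 indel_rate = indel_rate, molecule = molecule,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Draw a random ancestor sequence
#'
#' I.i.d. residues from the given composition (uniform over the alphabet
#' by default); reproducible for a fixed seed.
#'
#' @param length Sequence length (>= 10).
#' @param molecule Molecule type.
#' @param composition Optional named probability vector over the alphabet.
#' @param seed RNG seed.
#' @param id Record id.
#' @return A [seq_record()].
#' @export
generate_ancestor <- function(length, molecule = c("protein", "dna", "rna"),
                              composition = NULL, seed = 1L,
                              id = "ancestor") {
  molecule <- match.arg(molecule)
  if (length < 10) stop("ancestor length must be >= 10")
  sym <- residue_alphabet(molecule)$symbols
  if (is.null(composition)) {
    composition <- rep(1 / base::length(sym), base::length(sym))
    names(composition) <- sym
  } else {
    if (!setequal(names(composition), sym))
      stop("composition must be named by the full alphabet")
    if (abs(sum(composition) - 1) > 1e-6)
      stop("composition must sum to 1")
    composition <- composition[sym]
  }
  res <- with_seed(seed,
    paste(sample(sym, length, replace = TRUE, prob = composition),
          collapse = ""))
  seq_record(id, res, molecule)
}

# one batch of edits on a residue character vector
mutate_batch <- function(chars, n_subs, indel_rate, sym) {
  n <- length(chars)
  if (n_subs > 0) {
    pos <- sample.int(n, min(n_subs, n))
    for (p in pos) {
      chars[p] <- sample(setdiff(sym, chars[p]), 1L)
    }
  }
  if (indel_rate > 0) {
    n_indel <- stats::rbinom(1L, length(chars), indel_rate)
    for (k in seq_len(n_indel)) {
      if (length(chars) <= 10) break
      if (stats::runif(1) < 0.5) {
        chars <- chars[-sample.int(length(chars), 1L)]       # deletion
      } else {
        at <- sample.int(length(chars) + 1L, 1L)             # insertion
        chars <- append(chars, sample(sym, 1L), after = at - 1L)
      }
    }
  }
  chars
}

#' Mutate a sequence to a target identity band
#'
#' Applies batches of uniform point substitutions (and indels at
#' `indel_rate` per site per batch) to the sequence, re-measuring the
#' global-alignment identity to the source after each batch with the
#' package's own aligner, and stops as soon as the measured identity lies
#' in `[target - tolerance, target + tolerance]`. The batch size shrinks
#' as the target is approached to avoid overshoot; if the band is
#' overshot, mutation restarts from the source with smaller batches.
#'
#' @param seq Source [seq_record()].
#' @param target_identity Target percent identity (< 100 must be reachable
#'   within the tolerance; target 100 with tolerance 0 returns a copy).
#' @param tolerance Half-band in percent.
#' @param indel_rate Per-site indel rate per batch.
#' @param seed RNG seed.
#' @param id Id for the mutant record.
#' @param max_iter Batch budget before giving up.
#' @return A [seq_record()] with attribute `realized_identity`.
#' @export
mutate_to_identity <- function(seq, target_identity, tolerance = 3,
                               indel_rate = 0, seed = 1L,
                               id = paste0(seq$id, "_mut"),
                               max_iter = 400L) {
  stopifnot(inherits(seq, "seq_record"))
  if (target_identity >= 100 - 1e-9) {
    out <- seq_record(id, seq$residues, seq$molecule)
    attr(out, "realized_identity") <- 100
    return(out)
  }
  sym <- residue_alphabet(seq$molecule)$symbols
  src_chars <- seq_chars(seq)
  n <- length(src_chars)
  with_seed(seed, {
    chars <- src_chars
    shrink <- 1
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        stop(sprintf("mutate_to_identity: no convergence to %g +- %g after %d batches; increase the tolerance",
                     target_identity, tolerance, max_iter))
      mut <- paste(chars, collapse = "")
      ident <- align(seq$residues, mut, "global",
                     molecule = seq$molecule)$identity_pct
      if (ident >= target_identity - tolerance &&
          ident <= target_identity + tolerance) break
      if (ident < target_identity - tolerance) {   # overshot: restart finer
        chars <- src_chars
        shrink <- shrink * 2
        next
      }
      gap <- ident - target_identity
      n_subs <- max(1L, floor(n * gap / 100 / (2 * shrink)))
      chars <- mutate_batch(chars, n_subs, indel_rate, sym)
    }
    out <- seq_record(id, paste(chars, collapse = ""), seq$molecule)
    attr(out, "realized_identity") <- ident
    out
  })
}

#' Fisher-Yates shuffle of a sequence (composition-preserving negative)
#' @param seq A [seq_record()].
#' @param seed RNG seed.
#' @param id Id for the shuffled record.
#' @return A [seq_record()] with exactly the source's residue multiset.
#' @export
shuffle_sequence <- function(seq, seed = 1L, id = paste0(seq$id, "_shuf")) {
  chars <- seq_chars(seq)
  res <- with_seed(seed, paste(sample(chars), collapse = ""))
  seq_record(id, res, seq$molecule)
}

#' Generate a labeled remote-homology benchmark
#'
#' Positives: `spec$n_members` family members mutated independently from
#' one ancestor (star phylogeny) into the spec's identity band. Negatives:
#' either composition-preserving Fisher-Yates shuffles of the positives
#' (cycled when `n_negatives` exceeds the family size) or i.i.d. draws
#' from the positives' pooled residue composition. All member seeds are
#' derived deterministically from `spec$seed` and recorded, with realized
#' identities, in the manifest.
#'
#' @param spec A [family_spec()].
#' @param n_negatives Number of negatives (>= 1).
#' @param negative_mode `"shuffle"` or `"iid_background"`.
#' @return List with `records` (positives then negatives), `labels`
#'   (`"positive"`/`"negative"`), `ancestor`, and `manifest` (data.frame:
#'   id, label, seed, realized identity vs ancestor where applicable).
#' @export
generate_benchmark <- function(spec, n_negatives = spec$n_members,
                               negative_mode = c("shuffle",
                                                 "iid_background")) {
  negative_mode <- match.arg(negative_mode)
  stopifnot(inherits(spec, "family_spec"))
  if (n_negatives < 1) stop("n_negatives must be >= 1")
  anc <- generate_ancestor(spec$ancestor_length, spec$molecule,
                           seed = spec$seed)
  pos <- vector("list", spec$n_members)
  ident <- numeric(spec$n_members)
  for (i in seq_len(spec$n_members)) {
    s <- (spec$seed * 1000L + i) %% .Machine$integer.max
    pos[[i]] <- mutate_to_identity(anc, spec$target_identity,
                                   spec$identity_tolerance,
                                   spec$indel_rate, seed = s,
                                   id = sprintf("pos%03d", i))
    ident[i] <- attr(pos[[i]], "realized_identity")
  }
  neg <- vector("list", n_negatives)
  if (negative_mode == "shuffle") {
    for (i in seq_len(n_negatives)) {
      src <- pos[[(i - 1L) %% spec$n_members + 1L]]
      s <- (spec$seed * 1000L + 500000L + i) %% .Machine$integer.max
      neg[[i]] <- shuffle_sequence(src, seed = s, id = sprintf("neg%03d", i))
    }
  } else {
    pooled <- table(factor(unlist(lapply(pos, seq_chars)),
                           levels = residue_alphabet(spec$molecule)$symbols))
    comp <- as.numeric(pooled) / sum(pooled)
    names(comp) <- names(pooled)
    for (i in seq_len(n_negatives)) {
      s <- (spec$seed * 1000L + 500000L + i) %% .Machine$integer.max
      neg[[i]] <- generate_ancestor(spec$ancestor_length, spec$molecule,
                                    composition = comp, seed = s,
                                    id = sprintf("neg%03d", i))
    }
  }
  records <- c(pos, neg)
  labels <- c(rep("positive", spec$n_members),
              rep("negative", n_negatives))
  manifest <- data.frame(
    id = vapply(records, function(r) r$id, ""),
    label = labels,
    seed = c((spec$seed * 1000L + seq_len(spec$n_members)),
             (spec$seed * 1000L + 500000L + seq_len(n_negatives))),
    realized_identity = c(ident, rep(NA_real_, n_negatives)))
  list(records = records, labels = labels, ancestor = anc,
       manifest = manifest)
}
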