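# Regularization of variant representation: split multi-allelic records
# and decompose complex REF/ALT pairs into allelic primitives (SNPs and
# anchored simple indels) via global pairwise alignment, so that the
# same underlying variant is represented identically regardless of the
# caller that emitted it.

#' Split multi-allelic records
#'
#' Produces one biallelic record per ALT allele actually carried by the
#' genotype; ALT alleles present in no genotype allele are dropped, and
#' genotype indices are remapped to `{0, 1}`. A record whose genotype is
#' hom-ref (`0/0`) yields no output.
#'
#' @param x A [callset()].
#' @return A [callset()] in which every record has a single ALT allele.
#' @export
split_multiallelic <- function(x) {
  if (nrow(x) == 0L) return(x)
  alts <- strsplit(x$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  simple <- n_alt == 1L & x$gt2 >= 1L
  out_simple <- x[simple]
  rows <- which(!simple)
  if (length(rows)) {
    pieces <- lapply(rows, function(i) {
      carried <- sort(unique(c(x$gt1[i], x$gt2[i])))
      carried <- carried[carried >= 1L]
      if (length(carried) == 0L) return(NULL)
      rbindlist(lapply(carried, function(k) {
        g <- c(x$gt1[i], x$gt2[i])
        g <- ifelse(g == k, 1L, 0L)
        r <- as.list(x[i])
        r$alt <- alts[[i]][k]
        r$gt1 <- min(g); r$gt2 <- max(g)
        r
      }))
    })
    out_multi <- rbindlist(pieces)
    out <- rbind(out_simple, out_multi)
  } else {
    out <- out_simple
  }
  if (nrow(out)) setorder(out, chrom, pos)
  as_callset(out)
}

# alignment scoring for decomposition: match +1, mismatch -1,
# first gap base -2, each further base -1 (Biostrings penalties
# gapOpening = 1, gapExtension = 1)
.decomp_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE)
    }
    m
  }
})

# align alt (pattern) against ref (subject); returns gapped strings
align_pair <- function(ref, alt) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = alt, subject = ref, type = "global",
    substitutionMatrix = .decomp_submat(),
    gapOpening = 1, gapExtension = 1)
  list(p = strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]],
       s = strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]])
}

# left-align a deletion: ref window w (chars), deletion of k bases
# starting at 1-based index s; returns the leftmost equivalent s.
# Shifts never cross a base already touched by an earlier primitive
# (bound), since shift equivalence holds on the untouched reference
# only.
left_shift_del <- function(w, s, k, bound = 0L) {
  # deleting w[s..s+k-1] equals deleting w[s-1..s+k-2] iff
  # w[s-1] == w[s+k-1]
  while (s >= 2L && s - 1L > bound && w[s - 1L] == w[s + k - 1L]) {
    s <- s - 1L
  }
  s
}

# left-align an insertion: insertion of seq I (chars) after 1-based
# boundary b in window w; rotate left while the last inserted char
# matches the reference base at the boundary; same bound as above
left_shift_ins <- function(w, b, I, bound = 0L) {
  while (b >= 2L && b > bound && w[b] == I[length(I)]) {
    I <- c(w[b], I[-length(I)])
    b <- b - 1L
  }
  list(b = b, I = I)
}

decompose_one <- function(pos, ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  # fast paths: already primitive
  if (lr == 1L && la == 1L) {
    return(data.table(pos = pos, ref = ref, alt = alt))
  }
  rc <- strsplit(ref, "")[[1L]]
  ac <- strsplit(alt, "")[[1L]]
  if ((lr == 1L || la == 1L) && rc[1L] == ac[1L] && ref != alt) {
    return(data.table(pos = pos, ref = ref, alt = alt))  # anchored simple indel
  }
  g <- align_pair(ref, alt)
  p <- g$p; s <- g$s
  L <- length(p)
  out_pos <- integer(); out_ref <- character(); out_alt <- character()
  emit <- function(po, re, al) {
    out_pos[[length(out_pos) + 1L]] <<- po
    out_ref[[length(out_ref) + 1L]] <<- re
    out_alt[[length(out_alt) + 1L]] <<- al
  }
  i <- 1L
  roff <- 0L     # ref bases consumed so far (0-based offset of next ref base)
  touched <- 0L  # rightmost 1-based ref index claimed by an earlier primitive
  while (i <= L) {
    if (s[i] != "-" && p[i] != "-") {
      if (s[i] != p[i]) {
        emit(pos + roff, s[i], p[i])  # SNP
        touched <- roff + 1L
      }
      roff <- roff + 1L
      i <- i + 1L
    } else if (s[i] == "-") {
      # insertion run: alt bases with no ref partner
      j <- i
      while (j <= L && s[j] == "-") j <- j + 1L
      ins <- p[i:(j - 1L)]
      if (roff >= 1L) {
        sh <- left_shift_ins(rc, roff, ins, bound = touched)
        b <- sh$b
        emit(pos + b - 1L, rc[b], paste0(rc[b], paste(sh$I, collapse = "")))
      } else {
        # no left anchor: right-anchored insertion before the first ref base
        emit(pos, rc[1L], paste0(paste(ins, collapse = ""), rc[1L]))
      }
      touched <- max(touched, roff)
      i <- j
    } else {
      # deletion run: ref bases with no alt partner
      j <- i
      while (j <= L && p[j] == "-") j <- j + 1L
      k <- j - i
      d0 <- roff + 1L  # 1-based index of first deleted ref base
      if (d0 >= 2L) d0 <- left_shift_del(rc, d0, k, bound = touched)
      if (d0 >= 2L) {
        emit(pos + d0 - 2L,
             paste(rc[(d0 - 1L):(d0 + k - 1L)], collapse = ""),
             rc[d0 - 1L])
      } else {
        # no left anchor: right-anchored deletion ending on the next ref base
        emit(pos, paste(rc[1L:(k + 1L)], collapse = ""), rc[k + 1L])
      }
      touched <- roff + k
      roff <- roff + k
      i <- j
    }
  }
  data.table(pos = out_pos, ref = out_ref, alt = out_alt)
}

variant_class <- function(ref, alt) {
  fifelse(nchar(ref) == nchar(alt), "SNP",
          fifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
}

#' Decompose callset records into allelic primitives
#'
#' Splits multi-allelic records, then decomposes each REF/ALT pair into
#' its allelic primitives by global pairwise alignment (match +1,
#' mismatch -1, gap of length L costs 1 + L): aligned mismatches become
#' SNPs; gap runs become simple indels, left-aligned within the record's
#' REF window and anchored on the preceding reference base (or on the
#' following base when the gap opens the record, so no external genome
#' is needed). Applying all primitives of a record to its REF sequence
#' reconstructs the ALT exactly. Each primitive inherits the parent
#' record's QUAL, depth, genotype and labels; `parent_key` identifies
#' the source record. Records with `REF == ALT` are dropped with a
#' warning. Decomposition is idempotent: primitives pass through
#' unchanged.
#'
#' @param x A [callset()].
#' @return A `data.table` of class `c("primitive_callset", "callset")`
#'   with one row per primitive and columns `vclass`
#'   (`"SNP"`/`"INS"`/`"DEL"`) and `parent_key` in addition to the
#'   callset columns.
#' @export
decompose <- function(x) {
  x <- split_multiallelic(x)
  if (nrow(x) == 0L) {
    out <- copy(x)
    out[, `:=`(vclass = character(), parent_key = character())]
    setattr(out, "class", c("primitive_callset", class(x)))
    return(out[])
  }
  noop <- x$ref == x$alt
  if (any(noop)) {
    warning(sum(noop), " record(s) with REF == ALT dropped during ",
            "decomposition", call. = FALSE)
    x <- x[!noop]
  }
  simple_snp <- nchar(x$ref) == 1L & nchar(x$alt) == 1L
  simple_ind <- !simple_snp &
    (nchar(x$ref) == 1L | nchar(x$alt) == 1L) &
    substr(x$ref, 1L, 1L) == substr(x$alt, 1L, 1L)
  parent <- paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

  keep <- x[simple_snp | simple_ind]
  keep[, parent_key := parent[simple_snp | simple_ind]]

  complex_rows <- which(!(simple_snp | simple_ind))
  if (length(complex_rows)) {
    dec <- lapply(complex_rows, function(i) {
      prim <- decompose_one(x$pos[i], x$ref[i], x$alt[i])
      cbind(
        data.table(chrom = x$chrom[i]),
        prim,
        x[i, .(gt1, gt2, qual, depth, filter,
               caller_id, aligner_id, dataset_id)],
        data.table(parent_key = parent[i])
      )
    })
    out <- rbind(keep, rbindlist(dec), use.names = TRUE, fill = TRUE)
  } else {
    out <- keep
  }
  out[, vclass := variant_class(ref, alt)]
  setcolorder(out, c(CALLSET_COLS, "vclass", "parent_key"))
  setorder(out, chrom, pos, ref, alt)
  setattr(out, "class",
          unique(c("primitive_callset", "callset", class(out))))
  out[]
}
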