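#' Variant set
#'
#' A tibble of haploid variant records for one sample against one
#' reference: `chrom`, `pos` (1-based), `ref`, `alt`, `vclass`
#' (SNV/INS/DEL), `sample`. SNVs have two differing single bases; INS/DEL
#' carry the preceding anchor base in both alleles. Records are
#' deduplicated and sorted by `(chrom, pos, ref, alt)`.
#'
#' @param df Data frame with columns `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `vclass`, `sample`).
#' @param sample Sample (genome) label.
#' @param reference_id Reference genome label.
#' @return A tibble of class `mga_variants` with attributes `sample` and
#'   `reference_id`.
#' @export
mga_variants <- function(df, sample, reference_id) {
  df <- as_tibble(df)
  if (!nrow(df)) {
    df <- tibble(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), vclass = character(), sample = character())
  } else {
    df$pos <- as.integer(df$pos)
    if (is.null(df[["vclass"]]))
      df$vclass <- ifelse(nchar(df$ref) == 1 & nchar(df$alt) == 1, "SNV",
                          ifelse(nchar(df$alt) > nchar(df$ref), "INS", "DEL"))
    df$sample <- sample
    # INDELs share the anchor base with the longer allele; the anchor is
    # normally the first base, or the last base for block-leading runs
    first_shared <- substr(df$alt, 1, 1) == substr(df$ref, 1, 1)
    last_shared <- substr(df$alt, nchar(df$alt), nchar(df$alt)) ==
      substr(df$ref, nchar(df$ref), nchar(df$ref))
    bad <- (df$vclass == "SNV" & (nchar(df$ref) != 1 | nchar(df$alt) != 1 | df$ref == df$alt)) |
      (df$vclass == "INS" & (nchar(df$ref) != 1 | nchar(df$alt) <= nchar(df$ref) |
                               !(first_shared | last_shared))) |
      (df$vclass == "DEL" & (nchar(df$alt) != 1 | nchar(df$ref) <= nchar(df$alt) |
                               !(first_shared | last_shared)))
    if (any(bad))
      abort(paste0("malformed variant record(s) at row(s) ",
                   paste(head(which(bad), 5), collapse = ", ")))
    df <- distinct(df[c("chrom", "pos", "ref", "alt", "vclass", "sample")])
    df <- arrange(df, .data$chrom, .data$pos, .data$ref, .data$alt)
  }
  attr(df, "sample") <- sample
  attr(df, "reference_id") <- reference_id
  class(df) <- c("mga_variants", class(df))
  df
}

#' Extract variants from a projected pairwise alignment
#'
#' Column scan of each two-row + strand block (reference row first):
#' mismatch columns yield SNVs; maximal gap runs in the reference row
#' yield insertions and in the query row deletions, anchored on the
#' preceding reference base. A gap run at the very start of a block is
#' anchored on the first reference base of the block, with that base
#' included in both alleles. Columns where either row is `N` emit no SNV.
#'
#' @param blocks List of two-row [mga_block()] objects (from
#'   [align_genomes()] or [project_pairwise()]).
#' @param ref The reference [mga_genome()] (first row of every block).
#' @param sample Sample label for the query genome.
#' @return An [mga_variants()] tibble.
#' @export
extract_variants <- function(blocks, ref, sample) {
  out <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    if (!inherits(b, "mga_block") || nrow(b$rows) != 2)
      abort(paste0("block ", bi, " is not a two-row pairwise block"))
    if (b$rows$genome[1] != ref$genome_id)
      abort(paste0("block ", bi, " does not have the reference as its first row"))
    chrom <- b$rows$seq[1]
    cr <- column_positions(b$text[1], b$rows$start[1])
    cq <- column_positions(b$text[2], b$rows$start[2])
    rch <- cr$chars; qch <- cq$chars
    # SNVs
    mism <- which(cr$nongap & cq$nongap & rch != qch & rch != "N" & qch != "N")
    if (length(mism))
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom, pos = cr$pos[mism] + 1L, ref = rch[mism], alt = qch[mism],
        vclass = "SNV")
    # gap runs; immediately adjacent runs in the two rows (a junction
    # where unrelated material replaces a reference segment) are emitted
    # as a deletion and an insertion sharing one anchor base, so the pair
    # stays composable after normalization
    state <- ifelse(!cr$nongap, 1L, ifelse(!cq$nongap, 2L, 0L))
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    nz <- which(r$values != 0L)
    grp <- if (length(nz)) cumsum(c(TRUE, diff(nz) > 1L)) else integer(0)
    first_ref_pos <- b$rows$start[1] + 1L  # 1-based first ref base of block
    for (gi in unique(grp)) {
      segs <- nz[grp == gi]
      cols <- starts[segs[1]]:ends[segs[length(segs)]]
      del <- paste(rch[cols][state[cols] == 2L], collapse = "")
      ins <- paste(qch[cols][state[cols] == 1L], collapse = "")
      leading <- starts[segs[1]] == 1L
      if (!leading) {
        pos <- max(cr$pos[1:(starts[segs[1]] - 1L)], na.rm = TRUE) + 1L
        base <- seq_slice(ref, chrom, pos - 1L, pos)
        if (nchar(del))
          out[[length(out) + 1L]] <- tibble(chrom = chrom, pos = pos,
                                            ref = paste0(base, del), alt = base,
                                            vclass = "DEL")
        if (nchar(ins))
          out[[length(out) + 1L]] <- tibble(chrom = chrom, pos = pos,
                                            ref = base, alt = paste0(base, ins),
                                            vclass = "INS")
      } else {
        # block-leading runs anchor on the first reference base of the
        # block, included in both alleles
        if (nchar(del)) {
          del_pos1 <- min(cr$pos[cols], na.rm = TRUE) + 1L
          nxt <- del_pos1 + nchar(del)
          base <- seq_slice(ref, chrom, nxt - 1L, nxt)
          out[[length(out) + 1L]] <- tibble(chrom = chrom, pos = del_pos1,
                                            ref = paste0(del, base), alt = base,
                                            vclass = "DEL")
        }
        if (nchar(ins)) {
          base <- seq_slice(ref, chrom, first_ref_pos - 1L, first_ref_pos)
          out[[length(out) + 1L]] <- tibble(chrom = chrom, pos = first_ref_pos,
                                            ref = base, alt = paste0(ins, base),
                                            vclass = "INS")
        }
      }
    }
  }
  df <- if (length(out)) bind_rows(out) else
    tibble(chrom = character(), pos = integer(), ref = character(),
           alt = character(), vclass = character())
  mga_variants(df, sample = sample, reference_id = ref$genome_id)
}

# left-align-and-trim one indel; SNVs are already minimal. min_pos bounds
# the shift so a record never slides into the footprint of the record to
# its left (which would make the set non-composable)
normalize_one <- function(chrom, pos, ref_al, alt_al, genome, min_pos = 1L) {
  s <- genome$seq[[chrom]]
  repeat {
    changed <- FALSE
    # trim identical trailing bases (extending left when an allele empties)
    while (nchar(ref_al) > 1 && nchar(alt_al) > 1 &&
           substr(ref_al, nchar(ref_al), nchar(ref_al)) ==
             substr(alt_al, nchar(alt_al), nchar(alt_al))) {
      ref_al <- substr(ref_al, 1, nchar(ref_al) - 1)
      alt_al <- substr(alt_al, 1, nchar(alt_al) - 1)
      changed <- TRUE
    }
    if ((nchar(ref_al) == 1 || nchar(alt_al) == 1) &&
        substr(ref_al, nchar(ref_al), nchar(ref_al)) ==
          substr(alt_al, nchar(alt_al), nchar(alt_al)) &&
        nchar(ref_al) != nchar(alt_al) && pos > min_pos) {
      prev <- substr(s, pos - 1, pos - 1)
      ref_al <- paste0(prev, substr(ref_al, 1, nchar(ref_al) - 1))
      alt_al <- paste0(prev, substr(alt_al, 1, nchar(alt_al) - 1))
      pos <- pos - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  # trim identical leading bases beyond the anchor
  while (nchar(ref_al) > 1 && nchar(alt_al) > 1 &&
         substr(ref_al, 1, 1) == substr(alt_al, 1, 1) &&
         substr(ref_al, 2, 2) == substr(alt_al, 2, 2)) {
    ref_al <- substr(ref_al, 2, nchar(ref_al))
    alt_al <- substr(alt_al, 2, nchar(alt_al))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref_al, alt = alt_al)
}

#' Normalize variants to the leftmost parsimonious representation
#'
#' Standard left-align-and-trim: while both alleles end with the same base
#' the representation is shifted left by prepending the reference base
#' before `pos`; identical leading bases beyond the anchor are trimmed.
#' The result is unique and the operation idempotent. SNVs pass through
#' unchanged. A deletion and insertion sharing one anchor base (a joint
#' replacement emitted at non-homologous junctions) are trimmed jointly
#' and keep their shared anchor, because shifting the two independently
#' would make the pair non-composable.
#'
#' @param variants An [mga_variants()] tibble (or a single-row tibble).
#' @param genome The reference [mga_genome()].
#' @return The normalized [mga_variants()] tibble.
#' @export
normalize_variants <- function(variants, genome) {
  d <- as_tibble(variants)
  if (!nrow(d)) return(variants)
  # a deletion and an insertion sharing one anchor describe a joint
  # replacement; normalizing them independently can make the pair
  # non-composable, so they are trimmed jointly and keep a shared anchor
  key <- paste(d$chrom, d$pos)
  pair_del <- which(d$vclass == "DEL" & key %in% key[d$vclass == "INS"] &
                      substr(d$ref, 1, 1) == d$alt)
  paired <- rep(FALSE, nrow(d))
  drop <- rep(FALSE, nrow(d))
  for (i in pair_del) {
    j <- which(d$vclass == "INS" & key == key[i] & d$ref == substr(d$ref[i], 1, 1))
    if (length(j) != 1L) next
    p <- d$pos[i]
    W <- substr(d$ref[i], 2L, nchar(d$ref[i]))   # deleted window
    I <- substr(d$alt[j], 2L, nchar(d$alt[j]))   # inserted content
    while (nchar(W) >= 1 && nchar(I) >= 1 &&
           substr(W, nchar(W), nchar(W)) == substr(I, nchar(I), nchar(I))) {
      W <- substr(W, 1L, nchar(W) - 1L); I <- substr(I, 1L, nchar(I) - 1L)
    }
    while (nchar(W) >= 1 && nchar(I) >= 1 &&
           substr(W, 1, 1) == substr(I, 1, 1)) {
      p <- p + 1L
      W <- substr(W, 2L, nchar(W)); I <- substr(I, 2L, nchar(I))
    }
    if (nchar(W) && nchar(I)) {      # still a joint replacement: co-anchor
      base <- seq_slice(genome, d$chrom[i], p - 1L, p)
      d$pos[i] <- p; d$ref[i] <- paste0(base, W); d$alt[i] <- base
      d$pos[j] <- p; d$ref[j] <- base; d$alt[j] <- paste0(base, I)
      paired[c(i, j)] <- TRUE
    } else if (nchar(W)) {           # collapsed to a pure deletion
      base <- seq_slice(genome, d$chrom[i], p - 1L, p)
      d$pos[i] <- p; d$ref[i] <- paste0(base, W); d$alt[i] <- base
      drop[j] <- TRUE
    } else if (nchar(I)) {           # collapsed to a pure insertion
      base <- seq_slice(genome, d$chrom[j], p - 1L, p)
      d$pos[j] <- p; d$ref[j] <- base; d$alt[j] <- paste0(base, I)
      drop[i] <- TRUE
    } else {                         # the pair cancels entirely
      drop[c(i, j)] <- TRUE
    }
  }
  d <- d[!drop, ]
  paired <- paired[!drop]
  # normalize left to right, bounding each record's shift at the previous
  # record's footprint so the normalized set stays mutually composable
  ord <- order(d$chrom, d$pos)
  floor_by_chrom <- list()
  for (i in ord) {
    chrom <- d$chrom[i]
    fl <- floor_by_chrom[[chrom]] %||% 0L
    if (d$vclass[i] != "SNV" && !paired[i]) {
      have <- seq_slice(genome, chrom, d$pos[i] - 1L, d$pos[i] - 1L + nchar(d$ref[i]))
      if (have != d$ref[i])
        abort(sprintf("REF allele %s does not match reference at %s:%d",
                      d$ref[i], chrom, d$pos[i]))
      nv <- normalize_one(chrom, d$pos[i], d$ref[i], d$alt[i], genome,
                          min_pos = fl + 1L)
      d$pos[i] <- nv$pos; d$ref[i] <- nv$ref; d$alt[i] <- nv$alt
    }
    floor_by_chrom[[chrom]] <- max(fl, d$pos[i] + nchar(d$ref[i]) - 1L)
  }
  mga_variants(d, sample = attr(variants, "sample"),
               reference_id = attr(variants, "reference_id"))
}

#' Classify an INDEL as short or long
#'
#' Long means strictly longer than 50 bp
#' (`abs(nchar(ref) - nchar(alt)) > 50`); a 50 bp INDEL is short.
#'
#' @param variants An [mga_variants()] tibble of INS/DEL records (SNV rows
#'   are an error).
#' @return Character vector `"short"`/`"long"`, one per record.
#' @export
classify_indel <- function(variants) {
  d <- as_tibble(variants)
  if (any(d$vclass == "SNV")) abort("classify_indel is defined for INDELs only")
  len <- abs(nchar(d$ref) - nchar(d$alt))
  ifelse(len > 50, "long", "short")
}

#' Compare variant sets between methods
#'
#' Variants are matched on exact `(chrom, pos, ref, alt)`; returns the
#' count of every membership combination (the Venn cells) split by SNV
#' versus INDEL.
#'
#' @param sets Named list of normalized [mga_variants()] sets sharing one
#'   reference.
#' @return Tibble with columns `members` (e.g. `"A&B"`), `vclass`, `n`.
#' @export
compare_variant_sets <- function(sets) {
  refs <- unique(map_chr(sets, ~ attr(.x, "reference_id")))
  if (length(refs) > 1)
    abort(paste0("variant sets use different references: ", paste(refs, collapse = ", ")))
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  keyed <- lapply(names(sets), function(nm) {
    d <- as_tibble(sets[[nm]])
    if (!nrow(d)) return(tibble(key = character(), vclass = character(), method = character()))
    tibble(key = paste(d$chrom, d$pos, d$ref, d$alt, sep = ":"),
           vclass = ifelse(d$vclass == "SNV", "SNV", "INDEL"), method = nm)
  })
  all <- bind_rows(keyed)
  if (!nrow(all)) return(tibble(members = character(), vclass = character(), n = integer()))
  per_key <- summarise(group_by(all, .data$key, .data$vclass),
                       members = paste(sort(unique(.data$method)), collapse = "&"),
                       .groups = "drop")
  arrange(summarise(group_by(per_key, .data$members, .data$vclass),
                    n = n(), .groups = "drop"),
          .data$members, .data$vclass)
}

#' Apply a variant set to the reference
#'
#' Rebuilds the sample's sequence from the reference and its variant set.
#' Used for round-trip validation: over every projected block span the
#' reconstruction must equal the query genome exactly. Also returns, for
#' every output character, its origin position on the reference (`NA` for
#' inserted bases).
#'
#' @param genome Reference [mga_genome()].
#' @param variants An [mga_variants()] tibble against that reference.
#' @return List with `seq` (named character vector) and `origin` (list of
#'   integer vectors, 1-based reference positions or `NA`).
#' @export
apply_variants <- function(genome, variants) {
  d <- as_tibble(variants)
  seqs <- list(); origins <- list()
  for (chrom in names(genome$seq)) {
    s <- genome$seq[[chrom]]
    v <- d[d$chrom == chrom, ]
    # at one anchor position: substitute first, then skip the deleted run,
    # then append inserted bases (alignment column order)
    v <- v[order(v$pos, match(v$vclass, c("SNV", "DEL", "INS"))), ]
    pieces <- character(0); opieces <- list()
    cursor <- 1L
    emitted_to <- 0L  # highest reference position copied so far
    for (i in seq_len(nrow(v))) {
      p <- v$pos[i]
      # records sharing an anchor base compose cleanly: an insertion after
      # the last emitted reference base, or a deletion whose anchor was
      # already emitted (possibly substituted by an SNV at the same pos)
      ins_after_del <- v$vclass[i] == "INS" && p < cursor && p >= emitted_to
      del_at_anchor <- v$vclass[i] == "DEL" && p < cursor && p == emitted_to &&
        substr(v$ref[i], 1, 1) == v$alt[i]
      if (p < cursor && !ins_after_del && !del_at_anchor)
        abort(sprintf("overlapping variants at %s:%d", chrom, p))
      if (v$vclass[i] == "SNV") {
        if (p >= cursor) {
          if (p > cursor) {
            pieces <- c(pieces, substr(s, cursor, p - 1L))
            opieces <- c(opieces, list(cursor:(p - 1L)))
          }
          pieces <- c(pieces, v$alt[i]); opieces <- c(opieces, list(p))
          cursor <- p + 1L
          emitted_to <- p
        }
      } else if (v$vclass[i] == "DEL") {
        L <- nchar(v$ref[i]) - 1L
        end_anchored <- substr(v$ref[i], 1, 1) != v$alt[i]
        if (end_anchored) {       # deletes bases p..p+L-1, anchor base follows
          if (p > cursor) {
            pieces <- c(pieces, substr(s, cursor, p - 1L))
            opieces <- c(opieces, list(cursor:(p - 1L)))
            emitted_to <- p - 1L
          }
          cursor <- p + L
        } else {                  # standard: anchor at p, deletes p+1..p+L
          if (p >= cursor) {
            pieces <- c(pieces, substr(s, cursor, p))
            opieces <- c(opieces, list(cursor:p))
            emitted_to <- p
          }
          cursor <- max(cursor, p + L + 1L)
        }
      } else {  # INS
        end_anchored <- substr(v$alt[i], 1, 1) != v$ref[i]
        if (end_anchored && !ins_after_del) {  # inserted bases precede base p
          if (p > cursor) {
            pieces <- c(pieces, substr(s, cursor, p - 1L))
            opieces <- c(opieces, list(cursor:(p - 1L)))
            cursor <- p
            emitted_to <- p - 1L
          }
          ins <- substr(v$alt[i], 1L, nchar(v$alt[i]) - 1L)
        } else if (!ins_after_del) {  # standard: inserted bases follow base p
          if (p >= cursor) {
            pieces <- c(pieces, substr(s, cursor, p))
            opieces <- c(opieces, list(cursor:p))
            cursor <- p + 1L
            emitted_to <- p
          }
          ins <- substr(v$alt[i], 2L, nchar(v$alt[i]))
        } else {
          ins <- if (end_anchored) substr(v$alt[i], 1L, nchar(v$alt[i]) - 1L)
                 else substr(v$alt[i], 2L, nchar(v$alt[i]))
        }
        pieces <- c(pieces, ins)
        opieces <- c(opieces, list(rep(NA_integer_, nchar(ins))))
      }
    }
    if (cursor <= nchar(s)) {
      pieces <- c(pieces, substr(s, cursor, nchar(s)))
      opieces <- c(opieces, list(cursor:nchar(s)))
    }
    seqs[[chrom]] <- paste(pieces, collapse = "")
    org <- unlist(opieces)
    # expand single-base origins of substituted/copied chars to per-char
    origins[[chrom]] <- org
  }
  list(seq = unlist(seqs), origin = origins)
}
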