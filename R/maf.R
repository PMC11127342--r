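#' Alignment block (one MAF block)
#'
#' One multiple-alignment block: per-genome rows with source coordinates
#' (0-based start on the + strand of the source sequence, ungapped size,
#' strand, full source length) and equal-length gapped row texts.
#'
#' @param rows Tibble with columns `genome`, `seq`, `start`, `size`,
#'   `strand`, `src_size`.
#' @param text Character vector of gapped row texts, parallel to `rows`.
#' @return An object of class `mga_block`.
#' @export
mga_block <- function(rows, text) {
  rows <- as_tibble(rows)
  need <- c("genome", "seq", "start", "size", "strand", "src_size")
  if (!all(need %in% names(rows)))
    abort(paste0("missing block row columns: ", paste(setdiff(need, names(rows)), collapse = ", ")))
  if (nrow(rows) != length(text)) abort("one text per row required")
  if (length(unique(nchar(text))) > 1L) abort("row texts differ in length")
  nongap <- nchar(gsub("-", "", text, fixed = TRUE))
  if (any(nongap != rows$size))
    abort(paste0("row size disagrees with non-gap character count for row(s) ",
                 paste(which(nongap != rows$size), collapse = ", ")))
  if (any(rows$start + rows$size > rows$src_size))
    abort("row start + size exceeds source length")
  if (!all(rows$strand %in% c("+", "-"))) abort("row strand must be + or -")
  structure(list(rows = rows, text = text), class = "mga_block")
}

#' @export
print.mga_block <- function(x, ...) {
  cat(sprintf("<mga_block> %d rows x %d columns\n", nrow(x$rows), nchar(x$text[1])))
  for (i in seq_len(nrow(x$rows)))
    cat(sprintf("  %s.%s:%d+%d/%s\n", x$rows$genome[i], x$rows$seq[i],
                x$rows$start[i], x$rows$size[i], x$rows$strand[i]))
  invisible(x)
}

#' Write alignment blocks as MAF
#'
#' Emits the standard `a`/`s` line dialect. Row source names are written as
#' `genome.seq`.
#'
#' @param blocks List of [mga_block()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=twopiece", con)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (!inherits(b, "mga_block")) abort(paste0("block ", i, " is not an mga_block"))
    writeLines("", con)
    writeLines("a", con)
    src <- paste0(b$rows$genome, ".", b$rows$seq)
    writeLines(sprintf("s %s %d %d %s %d %s", src, b$rows$start, b$rows$size,
                       b$rows$strand, b$rows$src_size, b$text), con)
  }
  invisible(path)
}

#' Read a MAF file
#' @param path Path to a MAF file written in the `a`/`s` dialect.
#' @return List of [mga_block()] objects.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  blocks <- list()
  cur <- NULL
  flush_block <- function(cur) {
    if (is.null(cur) || !nrow(cur)) return(NULL)
    src <- str_split(cur$src, "\\.", n = 2)
    mga_block(tibble(genome = map_chr(src, 1), seq = map_chr(src, 2),
                     start = cur$start, size = cur$size, strand = cur$strand,
                     src_size = cur$src_size),
              cur$text)
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      b <- flush_block(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- tibble(src = character(), start = integer(), size = integer(),
                    strand = character(), src_size = integer(), text = character())
    } else if (startsWith(ln, "s")) {
      f <- str_split(trimws(ln), "\\s+")[[1]]
      if (length(f) < 7) abort(paste0("malformed MAF s line: ", ln))
      cur <- bind_rows(cur, tibble(src = f[2], start = as.integer(f[3]),
                                   size = as.integer(f[4]), strand = f[5],
                                   src_size = as.integer(f[6]), text = f[7]))
    }
  }
  b <- flush_block(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

# gapped text -> per-column source positions (0-based; NA at gap columns)
column_positions <- function(text, start) {
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  nong <- ch != "-"
  pos <- rep(NA_integer_, length(ch))
  pos[nong] <- start + seq_len(sum(nong)) - 1L
  list(chars = ch, pos = pos, nongap = nong)
}
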