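#' Build a character vocabulary from a corpus
#'
#' Enumerates every distinct character occurring in `corpus` in sorted order,
#' assigning contiguous integer indices starting at 1. Index 0 is reserved for
#' padding and the last index for unknown characters. Lookup is case-sensitive
#' (SMILES distinguishes aromatic `c` from aliphatic `C`).
#'
#' @param corpus Character vector of non-empty sequences.
#' @param alphabet_kind `"drug"` or `"protein"`; recorded for provenance.
#' @return An object of class `dpi_vocabulary`: a list with `char_to_index`
#'   (named integer vector), `pad_index` (always 0), `unk_index` (one past the
#'   last character index), `alphabet_kind` and `size` (number of embedding
#'   rows, i.e. `unk_index + 1`).
#' @examples
#' v <- build_vocabulary(c("CC", "CO"), "drug")
#' v$char_to_index   # C -> 1, O -> 2
#' @export
build_vocabulary <- function(corpus, alphabet_kind = c("drug", "protein")) {
  alphabet_kind <- match.arg(alphabet_kind)
  if (length(corpus) == 0L) {
    stop("empty corpus: no alphabet can be derived")
  }
  corpus <- as.character(corpus)
  if (any(is.na(corpus)) || any(!nzchar(corpus))) {
    stop("corpus contains empty or missing sequences")
  }
  chars <- sort(unique(unlist(strsplit(corpus, "", fixed = TRUE), use.names = FALSE)),
                method = "radix")
  new_vocabulary(chars, alphabet_kind)
}

new_vocabulary <- function(chars, alphabet_kind) {
  idx <- seq_along(chars)
  names(idx) <- chars
  structure(
    list(
      char_to_index = idx,
      pad_index = 0L,
      unk_index = length(chars) + 1L,
      alphabet_kind = alphabet_kind,
      size = length(chars) + 2L
    ),
    class = "dpi_vocabulary"
  )
}

#' Canonical fixed vocabularies
#'
#' Fixed dictionaries so trained models are portable across datasets: a
#' 62-symbol SMILES character set (element letters, aromatic lowercase,
#' ring-closure digits, bond/branch/charge punctuation) and a 25-letter
#' amino-acid set (the 20 standard residues plus the ambiguity and rare
#' codes B, J, O, U, X).
#'
#' @return A `dpi_vocabulary`.
#' @rdname canonical_vocabularies
#' @export
smiles_vocabulary <- function() {
  chars <- c(
    strsplit("ABCDEFGHIKLMNOPRSTVWXYZ", "")[[1]],   # element letters
    strsplit("abcdegilnorstu", "")[[1]],            # aromatic / two-letter tails
    as.character(0:9),                              # ring closures, charges
    "#", "%", "(", ")", "+", "-", ".", "/", "=", "@", "[", "\\", "]", "*", ":"
  )
  chars <- sort(unique(chars), method = "radix")
  stopifnot(length(chars) == 62L)
  new_vocabulary(chars, "drug")
}

#' @rdname canonical_vocabularies
#' @export
protein_vocabulary <- function() {
  chars <- sort(unique(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         "B", "J", "O", "U", "X")), method = "radix")
  stopifnot(length(chars) == 25L)
  new_vocabulary(chars, "protein")
}

#' @export
print.dpi_vocabulary <- function(x, ...) {
  cat(sprintf("<dpi_vocabulary: %s, %d characters, pad=0, unk=%d>\n",
              x$alphabet_kind, length(x$char_to_index), x$unk_index))
  invisible(x)
}

#' Tokenize a sequence to fixed-length integer indices
#'
#' Converts each character to its vocabulary index, right-pads with the pad
#' index to `max_len`, truncates longer sequences (flagged), and maps
#' characters absent from the vocabulary to the unknown index (counted).
#'
#' @param sequence Non-empty string.
#' @param vocab A `dpi_vocabulary`.
#' @param max_len Fixed output length (>= 1).
#' @param warn Emit a warning when unknown characters are encountered.
#' @return A `dpi_tokens` list: `indices` (integer vector of length
#'   `max_len`), `original_length`, `truncated`, `n_unknown`.
#' @examples
#' v <- build_vocabulary(c("CCO"), "drug")
#' tokenize("CCO", v, 5)$indices   # 1 1 2 0 0
#' @export
tokenize <- function(sequence, vocab, max_len, warn = TRUE) {
  stopifnot(inherits(vocab, "dpi_vocabulary"), max_len >= 1L)
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  truncated <- length(chars) > max_len
  kept <- if (truncated) chars[seq_len(max_len)] else chars
  idx <- unname(vocab$char_to_index[kept])
  unknown <- is.na(idx)
  idx[unknown] <- vocab$unk_index
  if (warn && any(unknown)) {
    warning(sprintf("%d unknown character(s) mapped to unk_index (%s)",
                    sum(unknown), paste(unique(kept[unknown]), collapse = "")),
            call. = FALSE)
  }
  out <- integer(max_len)              # pad_index = 0 everywhere
  out[seq_along(idx)] <- idx
  structure(
    list(indices = out, original_length = length(idx),
         truncated = truncated, n_unknown = sum(unknown)),
    class = "dpi_tokens"
  )
}

#' Recover the string a token sequence encodes
#'
#' Inverse of [tokenize()] for in-vocabulary, non-truncated input: pad
#' positions are dropped and indices are mapped back to characters. The
#' unknown index renders as `"?"`.
#'
#' @param tok A `dpi_tokens` object or a plain integer vector.
#' @param vocab The `dpi_vocabulary` used to tokenize.
#' @return A string (possibly empty for an all-pad sequence).
#' @export
detokenize <- function(tok, vocab) {
  stopifnot(inherits(vocab, "dpi_vocabulary"))
  idx <- if (inherits(tok, "dpi_tokens")) tok$indices else as.integer(tok)
  idx <- idx[idx != vocab$pad_index]
  if (any(idx < 0L | idx > vocab$unk_index)) {
    stop("token index outside vocabulary range")
  }
  if (length(idx) == 0L) return("")
  chars <- character(length(idx))
  lookup <- names(vocab$char_to_index)
  is_unk <- idx == vocab$unk_index
  chars[!is_unk] <- lookup[idx[!is_unk]]
  chars[is_unk] <- "?"
  paste(chars, collapse = "")
}

#' Tokenize many sequences into a matrix
#'
#' @param sequences Character vector.
#' @inheritParams tokenize
#' @return A list with `indices` (n x max_len integer matrix), `lengths`
#'   (original lengths, capped at `max_len`), `truncated` (logical vector) and
#'   `n_unknown` (total unknown-character count).
#' @export
tokenize_matrix <- function(sequences, vocab, max_len, warn = TRUE) {
  n <- length(sequences)
  mat <- matrix(0L, n, max_len)
  lens <- integer(n)
  trunc <- logical(n)
  unk <- 0L
  for (i in seq_len(n)) {
    tk <- tokenize(sequences[[i]], vocab, max_len, warn = FALSE)
    mat[i, ] <- tk$indices
    lens[i] <- tk$original_length
    trunc[i] <- tk$truncated
    unk <- unk + tk$n_unknown
  }
  if (warn && unk > 0L) {
    warning(sprintf("%d unknown character(s) across %d sequence(s)", unk, n),
            call. = FALSE)
  }
  list(indices = mat, lengths = lens, truncated = trunc, n_unknown = unk)
}

#' Read or write a vocabulary as JSON
#'
#' The on-disk format is a flat JSON object mapping each character to its
#' index, with reserved keys `"__pad__"` and `"__unk__"`, plus
#' `"__alphabet_kind__"`.
#'
#' @param vocab A `dpi_vocabulary`.
#' @param path File path.
#' @rdname vocabulary_io
#' @export
write_vocabulary <- function(vocab, path) {
  obj <- as.list(vocab$char_to_index)
  obj[["__pad__"]] <- vocab$pad_index
  obj[["__unk__"]] <- vocab$unk_index
  obj[["__alphabet_kind__"]] <- vocab$alphabet_kind
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname vocabulary_io
#' @export
read_vocabulary <- function(path) {
  obj <- jsonlite::read_json(path)
  kind <- obj[["__alphabet_kind__"]]
  obj[["__pad__"]] <- NULL
  obj[["__unk__"]] <- NULL
  obj[["__alphabet_kind__"]] <- NULL
  idx <- unlist(obj)
  v <- new_vocabulary(names(idx)[order(idx)], kind)
  v
}
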