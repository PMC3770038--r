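#' Construct a coding matrix for multiclass decomposition
#'
#' OAA: C columns, column j has +1 in row j and -1 elsewhere. OAO:
#' C(C-1)/2 columns, one per unordered class pair (i < j in
#' lexicographic order), +1 for i, -1 for j, 0 elsewhere. ECOC
#' (exhaustive): 2^(C-1) - 1 columns generated canonically with class
#' 1 always positive, which excludes duplicate, complementary and
#' trivial columns by construction.
#'
#' @param strategy `"OAA"`, `"OAO"` or `"ECOC"`.
#' @param C number of classes (>= 2; for ECOC, small enough that
#'   2^(C-1) - 1 columns fit in memory, C <= 16 enforced).
#' @return a [CodeMatrix-class].
#' @export
makeCodeMatrix <- function(strategy = c("OAA", "OAO", "ECOC"), C) {
  strategy <- match.arg(strategy)
  C <- as.integer(C)
  if (C < 2) stop("at least two classes are required")
  M <- switch(strategy,
    OAA = {
      M <- matrix(-1L, C, C)
      diag(M) <- 1L
      M
    },
    OAO = {
      pairs <- utils::combn(C, 2)
      M <- matrix(0L, C, ncol(pairs))
      for (b in seq_len(ncol(pairs))) {
        M[pairs[1, b], b] <- 1L
        M[pairs[2, b], b] <- -1L
      }
      M
    },
    ECOC = {
      if (C > 16) stop("exhaustive ECOC is limited to C <= 16")
      B <- 2L^(C - 1L) - 1L
      M <- matrix(0L, C, B)
      M[1, ] <- 1L
      for (b in seq_len(B)) {
        # bits of b assign classes 2..C; set bits map to -1, so b >= 1
        # guarantees at least one -1 (no trivial column) and the fixed
        # class-1 row rules out complements
        bits <- as.integer(intToBits(b))[seq_len(C - 1L)]
        M[2:C, b] <- ifelse(bits == 1L, -1L, 1L)
      }
      M
    })
  rownames(M) <- paste0("class", seq_len(C))
  methods::new("CodeMatrix", entries = M, strategy = strategy)
}

#' Entries of a coding matrix
#' @param x a [CodeMatrix-class].
#' @return integer C x B matrix over \{+1, -1, 0\}.
#' @rdname codeEntries
#' @export
setMethod("codeEntries", "CodeMatrix", function(x) x@entries)

setMethod("show", "CodeMatrix", function(object) {
  cat("CodeMatrix (", object@strategy, "): ", nrow(object@entries),
      " classes x ", ncol(object@entries), " binary columns\n", sep = "")
})

#' Binarize multiclass labels for one coding column
#'
#' Samples of +1-coded classes become +1, of -1-coded classes -1;
#' samples of 0-coded classes are masked out (they do not participate
#' in that binary subtask).
#'
#' @param labels integer class codes in 1..C.
#' @param column one column of a coding matrix: integer vector of
#'   length C over \{+1, -1, 0\}.
#' @return list with `y` (+1/-1 vector, `NA` where masked) and `mask`
#'   (logical, `TRUE` = participates).
#' @export
binarizeLabels <- function(labels, column) {
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > length(column)))
    stop("labels outside 1..C for this code matrix")
  y <- as.integer(column)[labels]
  mask <- y != 0L
  y[!mask] <- NA_integer_
  list(y = y, mask = mask)
}
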