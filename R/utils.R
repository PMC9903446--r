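# Shared internal helpers.

.MISSING_CHARS <- c("N", "?")
.GAP_CHAR <- "-"

# Run code under a temporary RNG state; restores .Random.seed afterwards so
# seeded operations do not disturb the caller's stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Uppercase and validate a raw sequence string against the survey alphabet
# {A,C,G,T,N,?,-}; "?" is recoded to "N" so sequences fit DNAStringSet
# (both are treated as missing states throughout).
normalizeSequence <- function(x, context = "sequence") {
  x <- toupper(x)
  bad <- unique(strsplit(gsub("[ACGTN?-]", "", x), "")[[1]])
  if (length(bad))
    stop("invalid character(s) ", paste(dQuote(bad), collapse = ", "),
         " in ", context, call. = FALSE)
  chartr("?", "N", x)
}

# DNAStringSet / named character / character matrix -> character matrix
# (rows = sequences). Requires equal lengths.
asAlignmentMatrix <- function(x, what = "alignment") {
  if (is.matrix(x)) {
    m <- x
  } else {
    if (methods::is(x, "XStringSet")) x <- as.character(x)
    if (!is.character(x)) stop(what, " must be sequences or a character matrix")
    w <- nchar(x)
    if (length(unique(w)) != 1)
      stop("sequences have unequal lengths; align them first", call. = FALSE)
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  }
  m[m == "?"] <- "N"
  m
}

isMissingState <- function(m) m == "N" | m == "?"

# Internal: consistent stop() with sprintf formatting
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
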