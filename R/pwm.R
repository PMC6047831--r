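#' Read a position weight matrix from a minimal text format
#'
#' The format is one header line `>name` followed by four lines, one per base
#' (`A`, `C`, `G`, `T`), each holding the per-position frequencies separated
#' by whitespace. Frequencies are renormalized per column.
#'
#' @param path file path
#' @param pseudocount added to every frequency before renormalization
#'   (default 0; supply a small value for matrices containing zeros)
#' @return 4 x width numeric matrix with rownames A, C, G, T and a `name`
#'   attribute
#' @export
read_pwm <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (!startsWith(lines[1], ">")) stopf("PWM file must start with '>name'")
  name <- sub("^>\\s*", "", lines[1])
  rows <- lapply(lines[2:5], function(l) strsplit(l, "\\s+")[[1]])
  bases <- vapply(rows, `[[`, "", 1)
  if (!setequal(bases, c("A", "C", "G", "T")))
    stopf("PWM file must have one row per base A, C, G, T")
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(m) <- bases
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  m <- m + pseudocount
  m <- sweep(m, 2, colSums(m), "/")
  attr(m, "name") <- name
  m
}

#' Write a PWM in the minimal text format
#' @param pwm 4 x width matrix with rownames A, C, G, T
#' @param path file path
#' @param name header name (defaults to the matrix `name` attribute)
#' @export
write_pwm <- function(pwm, path, name = attr(pwm, "name") %||% "pwm") {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0(">", name), con)
  for (b in c("A", "C", "G", "T"))
    writeLines(paste(c(b, format(pwm[b, ], digits = 8)), collapse = " "), con)
  invisible(path)
}

#' Log-odds score of a sequence under a PWM
#'
#' Sum over positions of `log2(f[base, i] / background)`. The sequence must
#' have exactly the PWM width and contain only A/C/G/T.
#'
#' @param seq character scalar
#' @param pwm 4 x width frequency matrix
#' @param background per-base background frequency (default uniform 0.25)
#' @return numeric log2-odds score
#' @export
pwm_score <- function(seq, pwm, background = 0.25) {
  w <- ncol(pwm)
  if (nchar(seq) != w)
    stopf("sequence length %d does not match PWM width %d", nchar(seq), w)
  bases <- strsplit(toupper(seq), "")[[1]]
  if (any(!bases %in% c("A", "C", "G", "T")))
    stopf("non-ACGT base at a scored position")
  sum(log2(pwm[cbind(match(bases, rownames(pwm)), seq_len(w))] / background))
}

#' Splice-site strength score
#'
#' Scores a donor (9-mer: 3 exonic + 6 intronic nt) or acceptor (23-mer: 20
#' intronic + 3 exonic nt) sequence with a pluggable scorer. The default
#' scorer is a PWM log-odds model; any function of signature
#' `f(seq)` returning a numeric score (e.g. an adapter around an external
#' maximum-entropy tool) may be supplied instead.
#'
#' @param seq site sequence
#' @param side `"donor"` or `"acceptor"`
#' @param scorer a PWM matrix (used via [pwm_score()]) or a function
#' @return numeric score
#' @export
score_splice_site <- function(seq, side = c("donor", "acceptor"), scorer) {
  side <- match.arg(side)
  expected <- if (side == "donor") 9L else 23L
  if (nchar(seq) != expected)
    stopf("%s site must be %d nt, got %d", side, expected, nchar(seq))
  if (is.function(scorer)) return(scorer(seq))
  pwm_score(seq, scorer)
}

#' Maximum PWM log-score over a sequence window
#'
#' Slides the PWM over every offset of `seq` and returns the maximum log-odds
#' score; used for the SF1 branch-point-region binding model over the 150 nt
#' upstream of the 3' splice site.
#'
#' @param seq character scalar, length >= PWM width
#' @param pwm 4 x width frequency matrix
#' @param background background base frequency
#' @return maximum log2-odds score over all offsets
#' @export
scan_pwm_max <- function(seq, pwm, background = 0.25) {
  w <- ncol(pwm)
  n <- nchar(seq)
  if (n < w) stopf("sequence (%d nt) shorter than PWM width (%d)", n, w)
  max(vapply(seq_len(n - w + 1L), function(i)
    pwm_score(substring(seq, i, i + w - 1L), pwm, background), 0))
}

#' @rdname scan_pwm_max
#' @export
scan_sf1_pwm <- scan_pwm_max

#' Built-in PWM configuration files
#'
#' Paths to the editable PWM text files shipped with the package: generic
#' consensus-shaped donor/acceptor splice-site matrices, a branch-point
#' heptamer matrix and an SF1 binding matrix. These are synthetic defaults
#' (authored for this package, not fitted to any organism) meant to be
#' replaced by user-supplied matrices for real analyses.
#'
#' @param which one of "donor", "acceptor", "branchpoint", "sf1"
#' @return file path
#' @export
default_pwm_file <- function(which = c("donor", "acceptor", "branchpoint",
                                       "sf1")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, "_synthetic.pwm"), package = "pirdep",
              mustWork = TRUE)
}
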