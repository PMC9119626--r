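#' Parse samtools text mpileup into allele observations
#'
#' Decodes the samtools text-pileup dialect, per line: chrom, 1-based
#' position, reference base, depth, base string, quality string
#' (Phred+33). In the base string, `.`/`,` count toward the reference base
#' and `ACGTacgt` toward themselves; `^` consumes the following
#' mapping-quality character; `$` is skipped; `+n...`/`-n...` indel
#' notations are consumed without contributing; `*`, `<`, `>` and `N`
#' occupy a quality slot but contribute no base count. Qualities pair
#' positionally with the decoded read-level symbols; a length mismatch is an
#' error naming the offending line.
#'
#' @param x path to an mpileup file, or a character vector of mpileup lines.
#' @param sample sample id attached to the observations.
#' @return allele-observation data.table (`sample`, `chrom`, `pos`,
#'   `count_A`..`count_T`, `qualsum_A`..`qualsum_T`).
#' @export
parse_mpileup <- function(x, sample) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) {
      if (length(f) >= 4L && as.integer(f[4]) == 0L) {
        rows[[ln]] <- data.table(sample = sample, chrom = f[1],
                                 pos = as.integer(f[2]),
                                 count_A = 0L, count_C = 0L, count_G = 0L,
                                 count_T = 0L, qualsum_A = 0, qualsum_C = 0,
                                 qualsum_G = 0, qualsum_T = 0)
        next
      }
      stop("malformed mpileup line ", ln)
    }
    ref <- toupper(f[3])
    bs <- strsplit(f[5], "")[[1]]
    qs <- utf8ToInt(f[6]) - 33L
    ## decode read-level symbols
    sym <- character(0)
    i <- 1L
    n <- length(bs)
    while (i <= n) {
      ch <- bs[i]
      if (ch == "^") {
        i <- i + 2L                      # caret + mapping quality
      } else if (ch == "$") {
        i <- i + 1L
      } else if (ch == "+" || ch == "-") {
        j <- i + 1L
        while (j <= n && bs[j] %in% as.character(0:9)) j <- j + 1L
        len <- as.integer(paste(bs[(i + 1L):(j - 1L)], collapse = ""))
        i <- j + len                     # skip inserted/deleted sequence
      } else {
        sym <- c(sym, ch)
        i <- i + 1L
      }
    }
    if (length(sym) != length(qs))
      stop("base/quality length mismatch on mpileup line ", ln,
           " (", length(sym), " read symbols vs ", length(qs),
           " quality characters)")
    counted <- toupper(sym)
    counted[sym %in% c(".", ",")] <- ref
    ok <- counted %in% bases
    cnt <- qsum <- setNames(numeric(4), bases)
    if (any(ok)) {
      tab <- tapply(rep(1L, sum(ok)), counted[ok], sum)
      cnt[names(tab)] <- tab
      qtab <- tapply(qs[ok], counted[ok], sum)
      qsum[names(qtab)] <- qtab
    }
    rows[[ln]] <- data.table(sample = sample, chrom = f[1],
                             pos = as.integer(f[2]),
                             count_A = as.integer(cnt["A"]),
                             count_C = as.integer(cnt["C"]),
                             count_G = as.integer(cnt["G"]),
                             count_T = as.integer(cnt["T"]),
                             qualsum_A = qsum[["A"]],
                             qualsum_C = qsum[["C"]],
                             qualsum_G = qsum[["G"]],
                             qualsum_T = qsum[["T"]])
  }
  rbindlist(rows)
}
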