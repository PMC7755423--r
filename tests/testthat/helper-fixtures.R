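# shared builders and independent oracles for the test suite

LOOPS <- c("cdr1l", "cdr2l", "cdr3l", "cdr1h", "cdr2h", "cdr3h")

# build a repertoire data.frame from loop strings (recycled)
makeRecords <- function(n, cdr1l = "ASTV", cdr2l = "GGS", cdr3l = "QQYN",
                        cdr1h = "GFTF", cdr2h = "ISSG", cdr3h = "ARDY",
                        reactivity = 0L, label = "unknown",
                        v_gene_h = NA_character_) {
  rec <- data.frame(id = sprintf("r%03d", seq_len(n)),
                    cdr1l = rep_len(cdr1l, n), cdr2l = rep_len(cdr2l, n),
                    cdr3l = rep_len(cdr3l, n), cdr1h = rep_len(cdr1h, n),
                    cdr2h = rep_len(cdr2h, n), cdr3h = rep_len(cdr3h, n),
                    reactivity_count = rep_len(as.integer(reactivity), n),
                    source = "test", v_gene_h = rep_len(v_gene_h, n),
                    v_gene_l = NA_character_, j_gene_h = NA_character_,
                    j_gene_l = NA_character_,
                    stringsAsFactors = FALSE)
  rec$label <- factor(rep_len(label, n),
                      levels = c("polyreactive", "non_polyreactive",
                                 "excluded", "unknown"))
  rec
}

writeTempCsv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# independent oracle: mutual information via the joint-histogram KL form
# sum_xy p(x,y) log2( p(x,y) / (p(x) p(y)) )
bruteMI <- function(x, y) {
  n <- length(x)
  tab <- table(x, y)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  total <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pxy <- tab[i, j] / n
    if (pxy > 0) total <- total + pxy * log2(pxy / (px[i] * py[j]))
  }
  unname(total)
}

# independent oracle: conditional entropy by direct enumeration over the
# joint table
bruteCondEntropy <- function(x, y) {
  n <- length(x)
  total <- 0
  for (yv in unique(y)) {
    sel <- y == yv
    py <- mean(sel)
    for (xv in unique(x[sel])) {
      pxy <- mean(sel & x == xv)
      total <- total - pxy * log2(pxy / py)
    }
  }
  unname(total)
}

# a small labeled repertoire with a loop-wide charged shift in cdr2h
strongSignalFixture <- function(nPerClass = 100L, delta = 0.5,
                                seed = 7L) {
  spec <- fixtureSpec(
    nPoly = nPerClass, nNon = nPerClass,
    shifts = if (delta > 0)
      list(list(loop = "cdr2h", positions = 0:7, residues = c("R", "K"),
                delta = delta, class = "polyreactive"))
    else list())
  generateRepertoire(spec, seed = seed)
}
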