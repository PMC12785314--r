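# Independent oracles and small fixture builders shared across tests.

# Naive O(n*m) both-strand restriction-site scanner, written independently
# of the package's regex-based engine: character-by-character IUPAC
# comparison at every offset.
naive_iupac <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

naive_find_cuts <- function(seq, motif, cut_top, cut_bottom) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  m_fwd <- strsplit(motif, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  m_rev <- rev(unname(comp[m_fwd]))
  m <- length(m_fwd)
  cuts <- integer(0)
  for (start in 0:(n - m)) {
    win <- s[(start + 1):(start + m)]
    if (all(mapply(function(b, code) b %in% naive_iupac[[code]], win, m_fwd)))
      cuts <- c(cuts, start + cut_top)
    if (all(mapply(function(b, code) b %in% naive_iupac[[code]], win, m_rev)))
      cuts <- c(cuts, start + m - cut_bottom)
  }
  as.integer(sort(unique(cuts[cuts > 0 & cuts < n])))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Minimal hand-built peak table: peaks as list(dye = c(size = height, ...))
make_table <- function(..., sample_id = "s1", run_id = "r1") {
  chan <- list(...)
  rows <- do.call(rbind, lapply(names(chan), function(d) {
    v <- chan[[d]]
    data.frame(dye = d, size = as.numeric(names(v)), height = unname(v))
  }))
  if (is.null(rows)) rows <- data.frame(dye = character(), size = numeric(),
                                        height = numeric())
  peak_table(sample_id, run_id, rows)
}

# A clean single-source electropherogram built by hand (not via the
# simulator) for caller unit tests. Genotype: F5 and F2 states as given,
# FGA 21/24, SE33 17/28.2, stutters at 7% of parents, digested controls.
hand_table <- function(f5 = "wt/wt", f2 = "wt/wt", h = 8000,
                       stutter_frac = 0.07) {
  cfg <- default_assay_config()
  fga <- .str_sizes(cfg, "FGA", c("21", "24"))
  se33 <- .str_sizes(cfg, "SE33", c("17", "28.2"))
  red <- numeric(0)
  if (f5 %in% c("wt/wt", "var/wt"))
    red["92"] <- if (f5 == "wt/wt") 2 * h else h
  if (f5 %in% c("var/wt", "var/var"))
    red["129"] <- if (f5 == "var/wt") 0.61 * h else 2 * h
  if (f2 %in% c("wt/wt", "var/wt"))
    red["246"] <- if (f2 == "wt/wt") 2 * h else h
  if (f2 %in% c("var/wt", "var/var"))
    red["226"] <- if (f2 == "var/wt") 0.67 * h else 2 * h
  green <- stats::setNames(c(h, h, stutter_frac * h, stutter_frac * h),
                           c(fga, fga - 4))
  blue <- stats::setNames(c(h, h, stutter_frac * h, stutter_frac * h),
                          c(se33, se33 - 4))
  make_table(red = red, green = green, blue = blue,
             black = c("276" = 2 * h))
}

.str_sizes <- function(cfg, locus_id, alleles) {
  loc <- NULL
  for (l in cfg$str_loci) if (l$locus == locus_id) loc <- l
  vapply(alleles, function(a) str_repeats_to_size(loc, a), numeric(1))
}
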