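# Small shared fixtures built in code.

toy_atlas <- function(n) {
  half <- ceiling(n / 2)
  hemi <- rep(c("L", "R"), c(half, n - half))
  abbr <- sprintf("N%02d", c(seq_len(half), seq_len(n - half)))
  atlas <- data.frame(index = seq_len(n) - 1L,
                      name = paste("Region", abbr, hemi),
                      abbreviation = abbr, hemisphere = hemi,
                      tissue_class = "cortical")
  atlas$label <- paste(abbr, hemi, sep = ".")
  atlas
}

toy_connectome <- function(w, subject_id = "toy") {
  connectome(w, toy_atlas(nrow(w)), subject_id = subject_id)
}

# Canonical small graphs (unit weights).
triangle_w <- function() {
  w <- matrix(1, 3, 3)
  diag(w) <- 0
  w
}

path3_w <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w
}

star_w <- function(leaves = 3) {
  n <- leaves + 1
  w <- matrix(0, n, n)
  w[1, 2:n] <- w[2:n, 1] <- 1
  w
}

complete_w <- function(n) {
  w <- matrix(1, n, n)
  diag(w) <- 0
  w
}
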