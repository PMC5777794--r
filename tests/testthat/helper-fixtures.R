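# shared fixture builders for the test suite

# expression matrix from a plain numeric matrix, auto-naming dimensions
make_xm <- function(vals, detected = NULL, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(vals)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(vals)))
  dimnames(vals) <- list(genes, samples)
  if (!is.null(detected)) dimnames(detected) <- dimnames(vals)
  expr_mat(vals, detected)
}

# two-group annotation: n1 SP then the rest split evenly into PF/ST
make_ann <- function(samples, n_sp) {
  n <- length(samples)
  n_ic <- n - n_sp
  data.frame(sample = samples,
             group = c(rep("SP", n_sp),
                       rep(c("PF", "ST"), length.out = n_ic)),
             age_class = "pediatric", study = "TEST",
             stringsAsFactors = FALSE)
}

# all permutations of 1..n as a matrix, one permutation per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# small random two-group dataset with optional planted effects
make_dataset <- function(n_genes = 50, n_sp = 3, n_ic = 5, n_de = 0,
                         effect = 2, sd = 0.5, seed = 1) {
  set.seed(seed)
  n <- n_sp + n_ic
  vals <- matrix(rnorm(n_genes * n, mean = 8, sd = sd), n_genes, n)
  if (n_de > 0)
    vals[seq_len(n_de), seq_len(n_sp)] <-
      vals[seq_len(n_de), seq_len(n_sp)] + effect
  xm <- make_xm(vals)
  list(xm = xm, ann = make_ann(sample_ids(xm), n_sp),
       de_genes = feature_ids(xm)[seq_len(n_de)])
}
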