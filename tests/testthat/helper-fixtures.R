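# Shared fixtures, built in code at test time.

quartet_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# A hand-written Roary-style CSV: 3 genomes, 4 families, one annotation with
# a quoted embedded comma, one cell with two semicolon-joined locus tags.
write_tiny_roary <- function(path) {
  meta <- paste(rep("x", 10), collapse = ",")
  lines <- c(
    paste0('"Gene","Non-unique Gene name","Annotation","No. isolates",',
           'x,x,x,x,x,x,x,x,x,x,"genA","genB","genC"'),
    sprintf('"fam1","","%s","3",%s,"t1","t2","t3"',
            "ABC transporter, permease", meta),
    sprintf('"fam2","","plain","2",%s,"t4","","t5"', meta),
    sprintf('"fam3","","two tags","1",%s,"t6;t7","",""', meta),
    sprintf('"fam4","","plain","2",%s,"","t8","t9"', meta))
  writeLines(lines, path)
  path
}

# unordered-pair keys for comparing significant pairs to the planted truth
pair_keys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

recovered_pairs <- function(sig, truth) {
  sum(pair_keys(truth$anchor, truth$partner) %in%
        pair_keys(sig$family_i, sig$family_j))
}

# a small matrix with planted structure, as a pam object
toy_pam <- function() {
  m <- matrix(0L, nrow = 4, ncol = 3,
              dimnames = list(c("A", "B", "C", "D"),
                              c("fam1", "fam2", "fam3")))
  m[c("A", "B"), "fam1"] <- 1L
  m[c("B", "C", "D"), "fam2"] <- 1L
  m[c("A", "D"), "fam3"] <- 1L
  pam(m)
}

# fabricate a significant-pairs frame in the shape run_pairwise emits
fake_sig_pairs <- function(i, j, p = 1e-10) {
  n <- length(i)
  data.frame(family_i = i, family_j = j, observed = rep_len(10L, n),
             expected = rep_len(2.5, n), p_raw = rep_len(p, n),
             significant = rep_len(TRUE, n), stringsAsFactors = FALSE)
}

fake_d_results <- function(families, D = NULL) {
  if (is.null(D)) D <- seq_along(families) / length(families)
  data.frame(family = families, D = D, stringsAsFactors = FALSE)
}
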