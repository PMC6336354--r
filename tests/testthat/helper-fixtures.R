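# shared fixtures built in code

# 40-residue disordered-like test sequence without proline or glycine
# (every residue carries all five nuclei)
test_sequence <- function() paste(rep("AKLSEDVRQM", 4), collapse = "")

# write a shift-table TSV and return its path
write_shift_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal NMR-STAR chemical-shift loop writer
write_nmrstar <- function(df, path = tempfile(fileext = ".str")) {
  three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  lines <- c("save_assigned_chemical_shifts", "loop_",
             "_Atom_chem_shift.Comp_index_ID", "_Atom_chem_shift.Comp_ID",
             "_Atom_chem_shift.Atom_ID", "_Atom_chem_shift.Val",
             sprintf("%d %s %s %.4f", df$residue_number,
                     three[df$residue_type], df$nucleus, df$shift),
             "stop_", "save_")
  writeLines(lines, path)
  path
}

# independent brute-force two-sided exact test using choose() ratios
brute_force_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# independent interval-enumeration oracle for binding-segment calls:
# candidate intervals [i, j] of below-threshold ok residues, every ok
# residue inside below threshold, no above-threshold residue inside, no
# two consecutive non-below residues inside, span >= min_length; keep
# maximal intervals only
brute_force_segments <- function(profile, threshold, min_length) {
  res <- profile$residue
  ok <- profile$status == "ok"
  below <- ok & !is.na(profile$ratio) & profile$ratio <= threshold
  above <- ok & !is.na(profile$ratio) & profile$ratio > threshold
  n <- length(res)
  valid <- function(i, j) {
    if (!below[i] || !below[j]) return(FALSE)
    inside <- i:j
    if (any(above[inside])) return(FALSE)
    gaps <- rle(!below[inside])
    if (any(gaps$values & gaps$lengths > 1)) return(FALSE)
    res[j] - res[i] + 1 >= min_length
  }
  cand <- list()
  for (i in seq_len(n)) for (j in i:n)
    if (valid(i, j)) cand[[length(cand) + 1L]] <- c(i, j)
  if (!length(cand)) return(data.frame(start_residue = integer(),
                                       end_residue = integer()))
  keep <- Filter(function(iv) {
    !any(vapply(cand, function(other)
      (other[1] < iv[1] && other[2] >= iv[2]) ||
      (other[1] <= iv[1] && other[2] > iv[2]), logical(1)))
  }, cand)
  out <- unique(do.call(rbind, lapply(keep, function(iv)
    data.frame(start_residue = res[iv[1]], end_residue = res[iv[2]]))))
  out[order(out$start_residue), , drop = FALSE]
}
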