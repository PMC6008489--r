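# shared fixture builders and independent oracles

extdata <- function(f) system.file("extdata", f, package = "fragscreen")

# write a toy fixed-column PDB from a data.frame with columns
# rec, name, alt, resn, chain, resno, x, y, z, occ, el
write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  fmt <- function(i) {
    a <- atoms[i, ]
    nm <- if (nchar(a$name) < 4) paste0(" ", formatC(a$name, width = -3)) else a$name
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$rec, i, nm, a$alt, a$resn, a$chain, a$resno,
            a$x, a$y, a$z, a$occ, 0, a$el)
  }
  writeLines(c(vapply(seq_len(nrow(atoms)), fmt, ""), "END"), path)
  path
}

toy_atom <- function(rec = "ATOM", name = "CA", alt = "", resn = "GLY",
                     chain = "A", resno = 1L, x = 0, y = 0, z = 0,
                     occ = 1, el = "C") {
  data.frame(rec = rec, name = name, alt = alt, resn = resn, chain = chain,
             resno = as.integer(resno), x = x, y = y, z = z, occ = occ,
             el = el, stringsAsFactors = FALSE)
}

# brute-force selectivity oracle: explicit double loop over cells
brute_score <- function(m, i = NULL, j = NULL, theta) {
  v <- if (!is.null(i)) m[i, ] else m[, j]
  hits <- 0L; eval_ <- 0L
  for (x in v) {
    if (is.na(x)) next
    eval_ <- eval_ + 1L
    if (x > theta) hits <- hits + 1L
  }
  list(hits = hits, evaluated = eval_,
       score = if (eval_ > 0) hits / eval_ else NaN)
}

# brute-force H-bond oracle: all-pairs loop with explicit arithmetic
brute_hbonds <- function(model, lig_sel, pro_sel, max_dist) {
  lig <- do.call(select_atoms, c(list(model), lig_sel))
  pro <- do.call(select_atoms, c(list(model), pro_sel))
  out <- NULL
  for (i in seq_len(nrow(lig))) {
    if (!lig$element[i] %in% c("N", "O")) next
    for (j in seq_len(nrow(pro))) {
      if (!pro$element[j] %in% c("N", "O")) next
      d <- sqrt((lig$x[i] - pro$x[j])^2 + (lig$y[i] - pro$y[j])^2 +
                  (lig$z[i] - pro$z[j])^2)
      if (d <= max_dist) {
        out <- rbind(out, data.frame(ligand_atom = lig$atom_name[i],
                                     protein_atom = pro$atom_name[j],
                                     protein_resno = pro$residue_number[j],
                                     distance = d, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) return(out)
  out[order(out$distance, out$protein_resno, out$protein_atom,
            out$ligand_atom), ]
}

# random molecular formula for round-trip property tests
random_formula <- function() {
  els <- sample(names(fragscreen::MONOISOTOPIC_MASS),
                sample(1:6, 1))
  counts <- sample(1:40, length(els), replace = TRUE)
  names(counts) <- els
  mol_formula(counts)
}
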