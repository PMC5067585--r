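# fixture builders used across test files: everything constructed in code

# a PDB text block for given atoms (list of lists with name, resn, chain,
# resi, x, y, z in Angstrom); optionally repeated over models
pdb_text <- function(atoms, models = 1L, drop_atom_in_model = NULL) {
  fmt <- function(a, serial) {
    rec <- if (identical(a$het, TRUE)) "HETATM" else "ATOM  "
    name <- if (nchar(a$name) >= 4L) sprintf("%-4s", a$name)
            else sprintf(" %-3s", a$name)
    sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            rec, serial, name, a$resn, a$chain, a$resi, a$x, a$y, a$z, 1, 0)
  }
  out <- character(0)
  for (m in seq_len(models)) {
    sel <- seq_along(atoms)
    if (!is.null(drop_atom_in_model) && m == drop_atom_in_model)
      sel <- sel[-length(sel)]
    block <- vapply(sel, function(i) fmt(atoms[[i]], i), character(1))
    if (models > 1L) block <- c(sprintf("MODEL     %4d", m), block, "ENDMDL")
    out <- c(out, block)
  }
  c(out, "END")
}

at <- function(name, resn, chain, resi, x, y, z, het = FALSE) {
  list(name = name, resn = resn, chain = chain, resi = resi,
       x = x, y = y, z = z, het = het)
}

write_pdb_text <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# single-frame ensemble straight from an atom spec (coordinates in nm)
frame_from_atoms <- function(df) {
  structuralEnsemble(
    df[, setdiff(names(df), c("x", "y", "z")), drop = FALSE],
    array(as.matrix(df[, c("x", "y", "z")]), c(nrow(df), 3L, 1L)))
}

# a serine donor (OG-HG) aimed at a glycine backbone O at distance d_nm,
# with the O displaced by angle_deg off the OG->HG axis at the donor
ser_gly_frame <- function(d_nm, angle_deg = 0) {
  th <- angle_deg * pi / 180
  data.frame(
    name = c("CB", "OG", "HG", "O"),
    element = c("C", "O", "H", "O"),
    res_name = c("SER", "SER", "SER", "GLY"),
    chain_id = "A", res_seq = c(1L, 1L, 1L, 2L),
    x = c(-0.15, 0, 0.1, d_nm * cos(th)),
    y = c(0, 0, 0, d_nm * sin(th)),
    z = 0, stringsAsFactors = FALSE) |> frame_from_atoms()
}
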