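# Hand-build raw RRF lines (2018AB layouts) for reader tests.

conso_line <- function(cui, lat, sab, tty, code, str, suppress = "N") {
  paste0(paste(cui, lat, "S", "L0000000", "PF", "S0000000", "Y", "A0000001",
               "", "", "", sab, tty, code, str, "0", suppress, "", sep = "|"),
         "|")
}

rel_line <- function(cui1, rel, cui2, rela, sab, suppress = "N") {
  paste0(paste(cui1, "", "CUI", rel, cui2, "", "CUI", rela, "R00000001", "",
               sab, sab, "", "", suppress, "", sep = "|"),
         "|")
}

write_tmp <- function(lines, name = "rrf") {
  path <- tempfile(name, fileext = ".RRF")
  writeLines(lines, path, useBytes = TRUE)
  path
}

# In-memory atom/relationship tables shaped like the reader outputs, for
# driving build_ontdag directly in unit tests.
mk_atoms <- function(cui, sab, str_name = paste("Concept", cui)) {
  data.table::data.table(cui = cui, lat = "ENG", sab = sab, tty = "PT",
                         code = paste0(sab, ":", sub("^C", "", cui)),
                         str_name = str_name, suppress = "N")
}

mk_rels <- function(child, parent, sab) {
  data.table::data.table(cui1 = child, rel = "PAR", cui2 = parent,
                         rela = "inverse_isa", sab = sab, suppress = "N")
}

mk_dags <- function(atoms, rels, sabs, ...) {
  build_ontdag(atoms, rels, source_config(included_sabs = sabs, ...))
}

# Load a generated fixture end-to-end through the readers.
load_fixture <- function(fx) {
  atoms <- read_mrconso(fx$mrconso, fx$config)
  rels <- read_mrrel(fx$mrrel, fx$config)
  dags <- suppressWarnings(build_ontdag(atoms, rels, fx$config))
  list(atoms = atoms, rels = rels, dags = dags)
}
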