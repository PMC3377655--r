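# All fixtures are generated in code; nothing is read from disk.

pdbLine <- function(record, serial, name, resName, chain, resNo, x, y, z,
                    occ = 1, element = "", altLoc = " ", insCode = " ") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altLoc, resName, chain, resNo, insCode,
          x, y, z, occ, 0, element)
}

# a 3-residue ALA-GLY-CYS chain plus a Zn ion, as raw PDB text
tinyPdbText <- function() {
  c(pdbLine("ATOM", 1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0, element = "N"),
    pdbLine("ATOM", 2, "CA", "ALA", "A", 1, 1.458, 0.0, 0.0, element = "C"),
    pdbLine("ATOM", 3, "C",  "ALA", "A", 1, 2.0, 1.4, 0.0, element = "C"),
    pdbLine("ATOM", 4, "N",  "GLY", "A", 2, 3.3, 1.5, 0.0, element = "N"),
    pdbLine("ATOM", 5, "CA", "GLY", "A", 2, 4.2, 2.6, 0.2, element = "C"),
    pdbLine("ATOM", 6, "C",  "GLY", "A", 2, 5.6, 2.1, 0.4, element = "C"),
    pdbLine("ATOM", 7, "N",  "CYS", "A", 3, 6.6, 3.0, 0.3, element = "N"),
    pdbLine("ATOM", 8, "CA", "CYS", "A", 3, 8.0, 2.7, 0.5, element = "C"),
    pdbLine("ATOM", 9, "C",  "CYS", "A", 3, 8.9, 3.9, 0.7, element = "C"),
    "TER",
    pdbLine("HETATM", 10, "ZN", "ZN", "A", 101, 10.0, 10.0, 10.0,
            element = "ZN"),
    "END")
}

# a helix with one planted Zn site, shared by several tests
smallSiteStructure <- function(n = 30, indices = c(5L, 6L, 9L), seed = 7) {
  ch <- makeBackbone(n, "helix", seed = seed)
  plantMetalSite(ch, "ZN", indices)
}

firstChain <- function(structure) {
  extractPolypeptideChains(structure, minLength = 1L)[[1L]]
}

# minimal hand-built pair set for correspondence-rule tests
manualPairSet <- function(i, j, fit, qset, tset) {
  P <- length(i)
  rot <- array(rep(diag(3), P), dim = c(3, 3, P))
  list(i = i, j = j, fitRmsd = fit, rot = rot,
       trans = matrix(0, P, 3), query = qset, template = tset)
}
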