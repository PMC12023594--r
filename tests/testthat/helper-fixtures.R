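# Shared fixture molecules and memoised heavyweight objects. The chemistry
# backend memoises perception per SMILES, so building these once per run
# keeps the backend subprocess count low.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# >= 50 drug-like molecules: three scaffold series plus assorted motifs
fixture_records <- function() {
  memo("fixture_records", {
    s1 <- make_series("O=C(N{R})Cc1ccc(Cl)cc1",
                      c("[H]", "C", "CC", "c2ccccc2", "C2CCCCC2", "Cc2ccccc2",
                        "CCO", "CC(C)C"),
                      seed = 11, name = "amide")
    s2 <- make_series("NC(=O)c1ccc({R})cc1",
                      c("Cl", "Br", "F", "C(F)(F)F", "C", "OC", "N", "O"),
                      seed = 12, name = "benzamide")
    s3 <- make_series("O=C(O)C({R})c1ccncc1",
                      c("[H]", "C", "CC", "CCC", "c2ccccc2", "CO"),
                      seed = 13, name = "acid")
    s4 <- make_series("{R}C(=O)N1CCCC1",
                      c("C", "CC", "c2ccccc2", "Cc2ccccc2", "C2CCCC2",
                        "c2ccc(Cl)cc2", "c2ccncc2", "CCC"),
                      seed = 14, name = "pyrrolidinone")
    extras <- tibble::tibble(
      compound_id = sprintf("misc_%02d", 1:22),
      smiles = c(
        "Cc1ccccc1", "c1ccccc1", "c1ccncc1", "C1CCCCC1", "c1ccc2ccccc2c1",
        "FC(F)(F)c1ccccc1", "CC(=O)Cl", "O=C1CCCCC1", "CC(=O)C", "CCO",
        "Nc1ccccc1", "OC(=O)CCc1ccccc1", "CC(C)Cc1ccc(C)cc1C(C)C(=O)O",
        "CC(=O)Nc1ccc(O)cc1", "Clc1ccc(CN2CCOCC2)cc1",
        "O=S(=O)(N)c1ccc(Cl)cc1", "CCOC(=O)c1ccccc1", "CN1CCCC1",
        "O=C(Nc1ccccc1)Nc1ccccc1", "CCN(CC)CCNC(=O)c1ccc(N)cc1",
        "Cn1cnc2ccccc21", "OCC1CCCO1"
      ),
      pic50 = round(seq(5.0, 9.2, length.out = 22), 2)
    )
    rbind(s1$records, s2$records, s3$records, s4$records, extras)
  })
}

fixture_rgs <- function() {
  memo("fixture_rgs", build_rgs(clean_dataset(fixture_records())))
}

demo_fixture <- function() memo("demo_fixture", make_series_demo(seed = 1))

demo_rgs <- function() {
  memo("demo_rgs", build_rgs(clean_dataset(demo_fixture()$records)))
}

amb_fixture <- function() memo("amb_fixture", make_ambiguous_pair_series(seed = 1))

amb_rgs <- function() {
  memo("amb_rgs", build_rgs(clean_dataset(amb_fixture()$records)))
}

rg_of <- function(smiles, id = "x") memo(paste0("rg:", smiles),
                                         assemble_rg(smiles, id))
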