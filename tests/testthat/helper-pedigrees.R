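# Shared fixtures: small hand-built pedigrees with analytically known
# kinship, and independent oracles (exhaustive label enumeration, manual BH).

trio_ped <- function(phen = c("unaffected", "affected", "affected")) {
  pedigree(family = "t1", id = c("p1", "p2", "c1"),
           father = c(NA, NA, "p1"), mother = c(NA, NA, "p2"),
           sex = c("male", "female", "female"), phenotype = phen)
}

# 2 founders + 3 children, all phenotyped
nuclear_ped <- function(phen = rep("unaffected", 5)) {
  pedigree(family = "n1", id = c("f", "m", "s1", "s2", "s3"),
           father = c(NA, NA, "f", "f", "f"),
           mother = c(NA, NA, "m", "m", "m"),
           sex = c("male", "female", "male", "female", "male"),
           phenotype = phen)
}

# 3-generation two-branch family: grandparents, two children with married-in
# spouses, one grandchild per branch (first cousins "ac" and "bc").
cousins_ped <- function(phen = rep("unaffected", 8)) {
  pedigree(
    family = "c1",
    id = c("gf", "gm", "a", "asp", "b", "bsp", "ac", "bc"),
    father = c(NA, NA, "gf", NA, "gf", NA, "a", "bsp"),
    mother = c(NA, NA, "gm", NA, "gm", NA, "asp", "b"),
    sex = c("male", "female", "male", "female", "female", "male",
            "male", "female"),
    phenotype = phen)
}

# child of two full siblings (inbred): phi(cc, cc) = 0.625
sibmating_ped <- function() {
  pedigree(
    family = "s1",
    id = c("f", "m", "b1", "b2", "cc"),
    father = c(NA, NA, "f", "f", "b1"),
    mother = c(NA, NA, "m", "m", "b2"),
    sex = c("male", "female", "male", "female", "male"),
    phenotype = "unaffected", validate = FALSE)
}

# 4-generation single lineage with married-in spouses at levels 2 and 3
lineage_ped <- function() {
  pedigree(
    family = "l1",
    id = c("g1f", "g1m", "g2", "g2sp", "g3", "g3sp", "g4a", "g4b", "g2b", "g2c"),
    father = c(NA, NA, "g1f", NA, "g2", NA, "g3", "g3", "g1f", "g1f"),
    mother = c(NA, NA, "g1m", NA, "g2sp", NA, "g3sp", "g3sp", "g1m", "g1m"),
    sex = c("male", "female", "male", "female", "male", "female",
            "male", "female", "female", "male"),
    phenotype = "unaffected")
}

# single small family drawn from the generator
random_family <- function(seed, generations = c(3, 4), mean_sibship = 2.5) {
  generate_pedigree(pedigree_spec(1, generations = generations,
                                  mean_sibship = mean_sibship, p_repro = 0.8),
                    seed = seed)
}
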