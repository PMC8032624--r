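# Profenofos (O-(4-bromo-2-chlorophenyl) O-ethyl S-propyl phosphorothioate).
# molecular_weight and logKow are literature values (PubChem; experimental
# logKow 4.44); profenofos has no ionizable group in the physiological range
# and is treated as neutral at pH 7.4.
# fup (fraction unbound in plasma) is NOT a measured value: it is derived from
# the Austin et al. (2002) lipophilicity-plasma-binding regression
# log((1-fu)/fu) = 0.56*logP - 1.41, giving fup = 0.078. Override it here if a
# measured value is available. blood_plasma_ratio defaults to 1 (see package
# documentation): model "blood" concentrations are plasma-equivalent.
name: profenofos
molecular_weight: 373.63
logKow: 4.44
pKa: .na
ionization: neutral
fup: 0.078
blood_plasma_ratio: 1.0
# Optional per-tissue partition-coefficient overrides, e.g.
# partition_overrides:
#   liver: 2.1
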