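# 4-bromo-2-chlorophenol (BCP), the hydrolysis product of profenofos, used by
# the rat model-evaluation sub-model. Properties are literature-order
# estimates, not measured in the source study: logKow ~3.0 (halogenated
# phenol), phenolic pKa ~7.8 (weak acid), fup from the same Austin (2002)
# regression applied to logD7.4. All user-overridable.
name: bcp
molecular_weight: 207.45
logKow: 3.0
pKa: 7.8
ionization: acid
fup: 0.40
blood_plasma_ratio: 1.0
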