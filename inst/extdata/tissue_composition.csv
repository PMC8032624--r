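# Fractional tissue composition (volume fractions) used for tissue:plasma
# partition-coefficient estimation by the tissue-composition method
# (Berezhkovskiy 2004 correction of Poulin & Theil 2002). Values are the
# standard human composition table of Poulin & Theil (2002), conventionally
# applied to both rat and human. water = fractional water content,
# neutral_lipid and phospholipid = fractional lipid contents.
# The 'plasma' row is the reference fluid; 'rest' uses muscle-like values.
tissue,water,neutral_lipid,phospholipid
liver,0.751,0.0348,0.0252
gut,0.718,0.0487,0.0163
fat,0.18,0.79,0.002
muscle,0.76,0.0238,0.0072
skin,0.718,0.0284,0.0111
bone,0.439,0.074,0.0011
brain,0.77,0.051,0.0565
heart,0.758,0.0115,0.0166
kidney,0.783,0.0207,0.0162
lung,0.811,0.003,0.009
spleen,0.788,0.0201,0.0198
rest,0.76,0.0238,0.0072
plasma,0.96,0.0035,0.00225
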