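file,md5
demirjian_scores_male.csv,4d550c4a9dc86b4db7d200b678f7026f
demirjian_scores_female.csv,a1e0218bca534c9568b6d91fed6cfa2b
nolla_age_norms_male_synthetic.csv,7ae2811546c1b261b602473e42f3e8d6
nolla_age_norms_female_synthetic.csv,1926f75f18c02f19bbee7f48137c25c0
demirjian_age_norms_male_synthetic.csv,b10961b90f698fcfc64e72adba5449e9
demirjian_age_norms_female_synthetic.csv,1e155ea5563315336566e9608add9b4a
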