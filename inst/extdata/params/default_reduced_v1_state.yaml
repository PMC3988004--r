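# default_reduced_v1 wild-type limit-cycle snapshot:
# state (a.u.) at a Per2 mRNA peak of the settled cycle, used as the
# default initial condition for this parameter set.
"Per1_mRNA": 4.79969741973
"Per2_mRNA":  4.4608952112
"Cry1_mRNA": 2.16818883618
"Cry2_mRNA":  4.2374056443
"Rev_mRNA":  1.1779941336
"Chrono_mRNA": 1.64273664221
"Bmal1_mRNA": 0.0344699416712
"PER_cyt": 0.01379607224
"CRY1_cyt": 11.5256511006
"CRY2_cyt": 18.5358441222
"CHRONO_cyt": 3.69113156347
"REV_nuc": 0.887551104538
"A_nuc": 0.294240957242
"CRY1:PER_cyt": 3.92170815309
"CRY2:PER_cyt":  4.1244953127
"CHRONO:PER_cyt": 0.696036962227
"CRY1:PER_nuc": 0.0641514748726
"CRY2:PER_nuc": 0.0663889547561
"CHRONO:PER_nuc": 0.0109909041034
"A:CRY1:PER_nuc": 25.0191738003
"A:CRY2:PER_nuc": 7.76567330211
"A:CHRONO:PER_nuc": 1.02939299418
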