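# Aqueous molar Gibbs free energies of formation, tabulated over temperature.
# SYNTHETIC table: linear dGf(T) = dHf(298.15 K) - T * dSf(298.15 K) anchored
# to standard-state aqueous formation properties from standard thermodynamic
# tables; generated by data-raw/make_gibbs_table.R. Intended for sign-level
# reaction energetics of the simplified formose pathway, not as a general
# thermodynamic reference.
# pressure_bar: 100
# units: J/mol; temperature grid in K
species	T_K	dGf_J_per_mol
water	270	-241737.09
water	290	-238470.95
water	310	-235204.81
water	330	-231938.67
water	350	-228672.53
water	370	-225406.39
water	390	-222140.25
water	410	-218874.11
water	430	-215607.96
water	450	-212341.82
water	470	-209075.68
water	490	-205809.54
water	510	-202543.40
water	530	-199277.26
water	550	-196011.12
water	570	-192744.98
water	590	-189478.83
water	610	-186212.69
formaldehyde	270	-107003.62
formaldehyde	290	-103803.89
formaldehyde	310	-100604.16
formaldehyde	330	-97404.43
formaldehyde	350	-94204.70
formaldehyde	370	-91004.96
formaldehyde	390	-87805.23
formaldehyde	410	-84605.50
formaldehyde	430	-81405.77
formaldehyde	450	-78206.04
formaldehyde	470	-75006.31
formaldehyde	490	-71806.57
formaldehyde	510	-68606.84
formaldehyde	530	-65407.11
formaldehyde	550	-62207.38
formaldehyde	570	-59007.65
formaldehyde	590	-55807.92
formaldehyde	610	-52608.18
acetaldehyde	270	-146545.13
acetaldehyde	290	-141681.80
acetaldehyde	310	-136818.48
acetaldehyde	330	-131955.16
acetaldehyde	350	-127091.83
acetaldehyde	370	-122228.51
acetaldehyde	390	-117365.19
acetaldehyde	410	-112501.86
acetaldehyde	430	-107638.54
acetaldehyde	450	-102775.21
acetaldehyde	470	-97911.89
acetaldehyde	490	-93048.57
acetaldehyde	510	-88185.24
acetaldehyde	530	-83321.92
acetaldehyde	550	-78458.59
acetaldehyde	570	-73595.27
acetaldehyde	590	-68731.95
acetaldehyde	610	-63868.62
acetic_acid	270	-404891.31
acetic_acid	290	-398901.04
acetic_acid	310	-392910.76
acetic_acid	330	-386920.49
acetic_acid	350	-380930.22
acetic_acid	370	-374939.94
acetic_acid	390	-368949.67
acetic_acid	410	-362959.40
acetic_acid	430	-356969.12
acetic_acid	450	-350978.85
acetic_acid	470	-344988.58
acetic_acid	490	-338998.30
acetic_acid	510	-333008.03
acetic_acid	530	-327017.76
acetic_acid	550	-321027.48
acetic_acid	570	-315037.21
acetic_acid	590	-309046.94
acetic_acid	610	-303056.66
ribose	270	-784671.07
ribose	290	-765224.48
ribose	310	-745777.90
ribose	330	-726331.31
ribose	350	-706884.72
ribose	370	-687438.14
ribose	390	-667991.55
ribose	410	-648544.96
ribose	430	-629098.37
ribose	450	-609651.79
ribose	470	-590205.20
ribose	490	-570758.61
ribose	510	-551312.02
ribose	530	-531865.44
ribose	550	-512418.85
ribose	570	-492972.26
ribose	590	-473525.67
ribose	610	-454079.09
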