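compound_id	neutral_formula	adduct	mz_calc_printed	mz_found_printed	known_discrepant	note
1d	C7H8N2O5	M+Na	223.0320	223.0325	TRUE	published calculated value off by 5e-4 from the electron-corrected sum (223.0325)
3a	C22H24N2O8	M+H	445.1605	445.1598	FALSE	NA
3b	C16H12N2O8	M+H	361.0662	361.0666	TRUE	published calculated value off by 4e-4 from the electron-corrected sum (361.0666)
3c	C14H10N4O6	M+H	403.2016	403.2013	TRUE	published ion formula (C25H27N2O3+) and m/z belong to a different molecule; compound formula gives 331.0673
3d	C18H26N4O6	M+Na	427.2380	417.1746	TRUE	published calculated value duplicates the 3e entry; formula gives 417.1744, consistent with the found value
3e	C19H28N4O6	M+NH4	427.2380	427.2374	TRUE	published ion formula C19H32N5O6+ evaluates to 426.2347, one mass unit below the printed pair
3f	C20H30N4O6	M+Na	445.2058	445.2049	FALSE	NA
3g	C18H24N2O6S2	M+NH4	446.1414	466.1409	FALSE	published found value has a 466/446 transposition typo; calculated value verifies
3h	C19H26N2O6S2	M+NH4	460.1571	466.1567	FALSE	published found value has a 466/460 transposition typo; calculated value verifies
3i	C16H20N2O6S2	M+K	439.0394	439.0391	FALSE	published calculated value contains a stray space but verifies numerically; excluded from the golden five by convention
3j	C12H12N2O6S2	M+H	345.0210	345.0211	FALSE	NA
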