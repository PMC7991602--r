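table,row,col,count,note
eh_presence_all,VM,present,2,EH present in 2/25 all-VM
eh_presence_all,VM,absent,23,complement of 2/25
eh_presence_all,MD,present,23,EH present in 23/29 all-MD
eh_presence_all,MD,absent,6,complement of 23/29
eh_presence_all,VM-MD,present,2,EH present in 2/8 VM-MD
eh_presence_all,VM-MD,absent,6,complement of 2/8
eh_presence_definite,VM,present,1,EH present in 1/19 definite VM
eh_presence_definite,VM,absent,18,complement of 1/19
eh_presence_definite,MD,present,12,EH present in 12/15 definite MD
eh_presence_definite,MD,absent,3,complement of 12/15
eh_presence_definite,VM-MD,present,2,EH present in 2/8 VM-MD
eh_presence_definite,VM-MD,absent,6,complement of 2/8
headache_all,VM,present,25,headache in 25/25 all-VM
headache_all,VM,absent,0,complement of 25/25
headache_all,MD,present,7,headache in 7/29 all-MD
headache_all,MD,absent,22,complement of 7/29
headache_all,VM-MD,present,5,headache in 5/8 VM-MD
headache_all,VM-MD,absent,3,complement of 5/8
headache_definite,VM,present,19,headache in 19/19 definite VM
headache_definite,VM,absent,0,complement of 19/19
headache_definite,MD,present,4,headache in 4/15 definite MD
headache_definite,MD,absent,11,complement of 4/15
headache_definite,VM-MD,present,5,headache in 5/8 VM-MD
headache_definite,VM-MD,absent,3,complement of 5/8
tinnitus_all,VM,none,14,25 minus 11 with tinnitus
tinnitus_all,VM,bilateral,7,bilateral tinnitus 7/25
tinnitus_all,VM,ipsilateral,4,ipsilateral tinnitus 4/25
tinnitus_all,MD,none,5,29 minus 24 with tinnitus
tinnitus_all,MD,bilateral,4,bilateral tinnitus 4/29
tinnitus_all,MD,ipsilateral,20,ipsilateral tinnitus 20/29
tinnitus_all,VM-MD,none,2,8 minus 6 with tinnitus
tinnitus_all,VM-MD,bilateral,1,bilateral tinnitus 1/8
tinnitus_all,VM-MD,ipsilateral,5,ipsilateral tinnitus 5/8
eh_location_by_deficit,no_eh,normal,19,location cross-tabulation row 1
eh_location_by_deficit,no_eh,vestibular,8,location cross-tabulation row 1
eh_location_by_deficit,no_eh,cochlear,6,location cross-tabulation row 1
eh_location_by_deficit,no_eh,vestibulocochlear,2,location cross-tabulation row 1 (row sums to 35 as printed)
eh_location_by_deficit,vestibular_eh,normal,0,location cross-tabulation row 2
eh_location_by_deficit,vestibular_eh,vestibular,1,location cross-tabulation row 2
eh_location_by_deficit,vestibular_eh,cochlear,0,location cross-tabulation row 2
eh_location_by_deficit,vestibular_eh,vestibulocochlear,0,location cross-tabulation row 2
eh_location_by_deficit,cochlear_eh,normal,4,location cross-tabulation row 3
eh_location_by_deficit,cochlear_eh,vestibular,2,location cross-tabulation row 3
eh_location_by_deficit,cochlear_eh,cochlear,2,location cross-tabulation row 3
eh_location_by_deficit,cochlear_eh,vestibulocochlear,4,location cross-tabulation row 3
eh_location_by_deficit,vestibular_and_cochlear_eh,normal,1,location cross-tabulation row 4
eh_location_by_deficit,vestibular_and_cochlear_eh,vestibular,2,location cross-tabulation row 4
eh_location_by_deficit,vestibular_and_cochlear_eh,cochlear,4,location cross-tabulation row 4
eh_location_by_deficit,vestibular_and_cochlear_eh,vestibulocochlear,7,location cross-tabulation row 4
eh_laterality_by_deficit_side,no_eh,normal,22,laterality cross-tabulation row 1 (row sums to 34 as printed)
eh_laterality_by_deficit_side,no_eh,right,3,laterality cross-tabulation row 1
eh_laterality_by_deficit_side,no_eh,left,5,laterality cross-tabulation row 1
eh_laterality_by_deficit_side,no_eh,bilateral,4,laterality cross-tabulation row 1
eh_laterality_by_deficit_side,right_eh,normal,4,laterality cross-tabulation row 2
eh_laterality_by_deficit_side,right_eh,right,8,laterality cross-tabulation row 2
eh_laterality_by_deficit_side,right_eh,left,1,laterality cross-tabulation row 2
eh_laterality_by_deficit_side,right_eh,bilateral,1,laterality cross-tabulation row 2
eh_laterality_by_deficit_side,left_eh,normal,0,laterality cross-tabulation row 3
eh_laterality_by_deficit_side,left_eh,right,0,laterality cross-tabulation row 3
eh_laterality_by_deficit_side,left_eh,left,9,laterality cross-tabulation row 3
eh_laterality_by_deficit_side,left_eh,bilateral,1,laterality cross-tabulation row 3
eh_laterality_by_deficit_side,bilateral_eh,normal,2,laterality cross-tabulation row 4
eh_laterality_by_deficit_side,bilateral_eh,right,1,laterality cross-tabulation row 4
eh_laterality_by_deficit_side,bilateral_eh,left,1,laterality cross-tabulation row 4
eh_laterality_by_deficit_side,bilateral_eh,bilateral,0,laterality cross-tabulation row 4
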