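scan_date,consignment,n_parcels,n_images,at2_outcome,at2_detected,at3_outcome,at3_detected
2023-12-21,18,1,1,Failed,0,Failed,0
2023-12-07,17,4,4,Failed,0,Partial,2
2023-12-05,16,1,1,Successful,1,Successful,1
2023-10-19,15,3,3,Failed,0,Partial,1
2023-10-11,14,1,1,Successful,1,Successful,1
2023-09-29,13,9,9,Partial,2,Partial,2
2023-09-26,12,3,3,Failed,0,Partial,1
2023-09-14,11,5,5,Partial,1,Successful,5
2023-09-08,10,5,5,Partial,1,Partial,2
2023-09-05,9,1,1,Successful,1,Successful,1
2023-09-01,8,3,3,Failed,0,Failed,0
2023-08-31,7,2,2,Failed,0,Successful,2
2023-08-25,6,2,2,Failed,0,Partial,1
2023-08-21,5,3,3,Partial,1,Successful,3
2023-08-18,4,1,1,Failed,0,Successful,1
2023-08-11,3,1,1,Successful,1,Successful,1
2023-08-07,2,1,1,Failed,0,Successful,1
2023-07-21,1,2,2,Partial,1,Successful,2
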