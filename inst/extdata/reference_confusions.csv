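form,family,set,true_grade,pred_1,pred_2,pred_3,reported_total_pct
sliced,svm,calibration,1,100,8,3,85.29
sliced,svm,calibration,2,12,77,22,85.29
sliced,svm,calibration,3,4,0,107,85.29
sliced,svm,prediction,1,36,3,0,83.76
sliced,svm,prediction,2,9,23,7,83.76
sliced,svm,prediction,3,0,0,39,83.76
sliced,rf,calibration,1,111,0,0,94.89
sliced,rf,calibration,2,1,104,6,94.89
sliced,rf,calibration,3,0,10,101,94.89
sliced,rf,prediction,1,31,8,0,73.50
sliced,rf,prediction,2,10,20,9,73.50
sliced,rf,prediction,3,0,4,35,73.50
intact,svm,calibration,1,35,2,0,96.40
intact,svm,calibration,2,1,35,1,96.40
intact,svm,calibration,3,0,0,37,96.40
intact,svm,prediction,1,13,0,0,100.00
intact,svm,prediction,2,0,13,0,100.00
intact,svm,prediction,3,0,0,13,100.00
intact,rf,calibration,1,37,0,0,100.00
intact,rf,calibration,2,0,37,0,100.00
intact,rf,calibration,3,0,0,37,100.00
intact,rf,prediction,1,13,0,0,94.87
intact,rf,prediction,2,2,11,0,94.87
intact,rf,prediction,3,0,0,13,94.87
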