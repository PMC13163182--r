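region_id,region_name,mni_x,mni_y,mni_z,network
R001,Left Angular Gyrus,-45.3,-62.3,33,DMN
R002,Left Cerebellum Lobules III-VI,-19.3,-54.3,-22.6,cerebellum
R003,Right Cerebellum Lobules III-VI,21.7,-54.1,-24,cerebellum
R004,Left Cerebellum Lobules I-II,-32.6,-71.9,-35.2,cerebellum
R005,Right Cerebellum Lobules I-II,35.3,-70.4,-36.2,cerebellum
R006,Left Cerebellum Lobules VII-X,-22.7,-55.7,-49.2,cerebellum
R007,Right Cerebellum Lobules VII-X,23.3,-57.5,-50.6,cerebellum
R008,Left Posterior Cingulate Cortex,-6,-44.5,22,DMN
R009,Right Posterior Cingulate Cortex,6.4,-43.5,19.2,DMN
R010,Left Inferior Frontal Gyrus (Triangular Part),-46.7,28.1,10.1,FPN
R011,Left Fusiform Gyrus,-31.9,-42.4,-23.1,visual
R012,Right Heschl Gyrus,45.1,-18.6,7.7,auditory
R013,Right Inferior Parietal Lobule,45.3,-47.5,47.2,salience
R014,Right Superior Parietal Lobule,24.8,-60.2,59.8,DAN
R015,Left Precuneus,-8.5,-57.4,45.5,DMN
R016,Right Precuneus,8.8,-57.4,41.3,DMN
R017,Right Supplementary Motor Area,7.2,-0.9,58.7,SMN
R018,Right Thalamus,12,-19.3,5.2,subcortical
R019,Cerebellar Vermis,1.2,-58.6,-20.1,cerebellum
R020,Synthetic Placeholder Region 01,-55.5,-45.7,24.7,unassigned
R021,Synthetic Placeholder Region 02,53.2,-20.8,6.3,unassigned
R022,Synthetic Placeholder Region 03,33.9,-8.3,-39.8,unassigned
R023,Synthetic Placeholder Region 04,42,60.1,11.4,unassigned
R024,Synthetic Placeholder Region 05,57.8,-5,-23.7,unassigned
R025,Synthetic Placeholder Region 06,30.8,49,39.5,unassigned
R026,Synthetic Placeholder Region 07,-38.9,-62.8,-18.4,unassigned
R027,Synthetic Placeholder Region 08,-62.8,-32.7,13.1,unassigned
R028,Synthetic Placeholder Region 09,61.5,-91.6,51,unassigned
R029,Synthetic Placeholder Region 10,-30.9,56.7,-22.5,unassigned
R030,Synthetic Placeholder Region 11,-50.8,-64,-43.1,unassigned
R031,Synthetic Placeholder Region 12,2,41.8,-36.4,unassigned
R032,Synthetic Placeholder Region 13,29.3,-75.6,7.7,unassigned
R033,Synthetic Placeholder Region 14,-4.7,60.8,-4.7,unassigned
R034,Synthetic Placeholder Region 15,-63.5,-25.7,46.1,unassigned
R035,Synthetic Placeholder Region 16,46.2,61.8,44.4,unassigned
R036,Synthetic Placeholder Region 17,-33.7,37.7,-11.3,unassigned
R037,Synthetic Placeholder Region 18,-50.6,15.8,36.8,unassigned
R038,Synthetic Placeholder Region 19,-51.6,-33.5,-5.5,unassigned
R039,Synthetic Placeholder Region 20,22.9,34.6,46.9,unassigned
R040,Synthetic Placeholder Region 21,5,55.4,-37.8,unassigned
R041,Synthetic Placeholder Region 22,-15.3,44.2,42.6,unassigned
R042,Synthetic Placeholder Region 23,-43.2,-9,-19.8,unassigned
R043,Synthetic Placeholder Region 24,12.9,-68.9,23.8,unassigned
R044,Synthetic Placeholder Region 25,-16.1,-86,-20.7,unassigned
R045,Synthetic Placeholder Region 26,-0.7,-42.4,-34.8,unassigned
R046,Synthetic Placeholder Region 27,-0.5,-7.8,-43.8,unassigned
R047,Synthetic Placeholder Region 28,49.9,-64.3,-12.7,unassigned
R048,Synthetic Placeholder Region 29,40.5,42.5,57,unassigned
R049,Synthetic Placeholder Region 30,-42.3,27.9,43.3,unassigned
R050,Synthetic Placeholder Region 31,33.8,-42.5,-2.2,unassigned
R051,Synthetic Placeholder Region 32,32.3,31.6,48.2,unassigned
R052,Synthetic Placeholder Region 33,24.3,14.9,57.6,unassigned
R053,Synthetic Placeholder Region 34,-53.2,28.1,21.2,unassigned
R054,Synthetic Placeholder Region 35,26.8,-71.6,9.4,unassigned
R055,Synthetic Placeholder Region 36,-49.1,32.1,-44.8,unassigned
R056,Synthetic Placeholder Region 37,35.3,41.8,55.4,unassigned
R057,Synthetic Placeholder Region 38,-9.2,-86.8,-38,unassigned
R058,Synthetic Placeholder Region 39,-63.8,-78.2,-27,unassigned
R059,Synthetic Placeholder Region 40,44.4,-63.4,54.6,unassigned
R060,Synthetic Placeholder Region 41,54.1,38.1,46.7,unassigned
R061,Synthetic Placeholder Region 42,-0.4,-20.3,3,unassigned
R062,Synthetic Placeholder Region 43,-29.5,-71.7,-27.4,unassigned
R063,Synthetic Placeholder Region 44,35.1,-87.9,-6.3,unassigned
R064,Synthetic Placeholder Region 45,31.8,-32.6,41.5,unassigned
R065,Synthetic Placeholder Region 46,-7.9,-24,66.7,unassigned
R066,Synthetic Placeholder Region 47,-8.1,48.5,34.2,unassigned
R067,Synthetic Placeholder Region 48,-1,44.5,68.4,unassigned
R068,Synthetic Placeholder Region 49,37.1,44,36.1,unassigned
R069,Synthetic Placeholder Region 50,-27,-40.3,-21.5,unassigned
R070,Synthetic Placeholder Region 51,-46.4,-66.7,-25.8,unassigned
R071,Synthetic Placeholder Region 52,-59.8,28.3,6.7,unassigned
R072,Synthetic Placeholder Region 53,-62.2,29.7,-21.7,unassigned
R073,Synthetic Placeholder Region 54,-52,-6.6,6.8,unassigned
R074,Synthetic Placeholder Region 55,33.1,3.3,3.4,unassigned
R075,Synthetic Placeholder Region 56,11.8,-67.2,63.5,unassigned
R076,Synthetic Placeholder Region 57,57.5,-8.5,57.2,unassigned
R077,Synthetic Placeholder Region 58,32,17,60.2,unassigned
R078,Synthetic Placeholder Region 59,-46.9,46.4,-37.3,unassigned
R079,Synthetic Placeholder Region 60,62.5,-58.7,-4.3,unassigned
R080,Synthetic Placeholder Region 61,-60.9,-89.9,40.6,unassigned
R081,Synthetic Placeholder Region 62,17.8,-24.1,-14.2,unassigned
R082,Synthetic Placeholder Region 63,-61.4,-74.2,-19.6,unassigned
R083,Synthetic Placeholder Region 64,46.6,-60,-11.8,unassigned
R084,Synthetic Placeholder Region 65,15.4,-11.5,34.1,unassigned
R085,Synthetic Placeholder Region 66,60.9,-5,-31.7,unassigned
R086,Synthetic Placeholder Region 67,-4.8,28.6,30.2,unassigned
R087,Synthetic Placeholder Region 68,-19.2,29,17.9,unassigned
R088,Synthetic Placeholder Region 69,-39.6,31.2,14.1,unassigned
R089,Synthetic Placeholder Region 70,9.5,-89.8,54.3,unassigned
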