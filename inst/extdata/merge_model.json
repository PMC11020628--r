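{
  "weights": [-1.32260681109021, -1.35503407908679, -4.49448650427103, -0.00681822792881298, -0.0216053258401874, -0.0522238246861527, 0.372753752774658, -0.149336307409857, 0.134588601228242, -0.197196603624572],
  "bias": -3.02894621043801,
  "feature_means": [228.973257698541, 228.437601296596, 8392.29740680713, 2860.16450567261, 0.886547811993517, 0.787079415152975, 1.89868755336806, 1.92521708947184, 0.522215853186478],
  "feature_sds": [286.355716203388, 285.532915758568, 15514.7504947621, 2595.23847547985, 0.928994386799436, 0.730610727881697, 1.2152667134609, 1.21480833377132, 0.935178019884848],
  "hyperparameters": {
    "loss": "hinge",
    "lambda": 3.32505779416694e-05,
    "eta0": 0.040758462811366,
    "epochs": 20
  },
  "cv_f1": 0.690181488135147,
  "validation_f1": 0.791111111111111,
  "test_metrics": [0.878048780487805, 0.580645161290323, 0.699029126213592],
  "version": "1"
}
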